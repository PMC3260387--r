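# metric extraction: hand-computed traces and aggregation conventions

# event log with two compression segments (10-70, 100-160) and ROSC at 160
two_segment_log <- function() {
  event_log(time = c(0, 0, 10, 70, 100, 160, 160),
            code = c("STATE", "RHYTHM", "CC_ON", "CC_OFF", "CC_ON",
                     "DEFIB", "ROSC"),
            detail = c("NO_CC", "cVF", "", "", "", "150J indicated", ""))
}

test_that("the assessment window ends at ROSC, else at the last record", {
  expect_equal(assessment_window(two_segment_log())[["end"]], 160)
  censored <- event_log(time = c(0, 600), code = c("RHYTHM", "STATE"),
                        detail = c("cVF", "EXIT"))
  expect_equal(assessment_window(censored)[["end"]], 600)
  expect_error(assessment_window(event_log()), "empty")
})

test_that("no-flow time is the hands-off time inside the window", {
  nf <- no_flow_metrics(two_segment_log())
  expect_equal(nf[["no_flow_time"]], 40)  # 0-10 and 70-100
  expect_equal(nf[["no_flow_time_fraction"]], 0.25)

  continuous <- event_log(time = c(0, 0, 300), code = c("RHYTHM", "CC_ON",
                                                        "STATE"),
                          detail = c("cVF", "", "EXIT"))
  nf <- no_flow_metrics(continuous)  # open segment closes at the window end
  expect_equal(nf[["no_flow_time"]], 0)
  expect_equal(nf[["no_flow_time_fraction"]], 0)

  untouched <- event_log(time = c(0, 600), code = c("RHYTHM", "STATE"),
                         detail = c("cVF", "EXIT"))
  nf <- no_flow_metrics(untouched)
  expect_equal(nf[["no_flow_time"]], 600)
  expect_equal(nf[["no_flow_time_fraction"]], 1.0)

  orphan <- event_log(time = c(0, 50, 100), code = c("RHYTHM", "CC_OFF",
                                                     "STATE"),
                      detail = c("cVF", "", "EXIT"))
  expect_error(no_flow_metrics(orphan), "CC_OFF without")
})

test_that("defibrillation metrics follow the interval arithmetic", {
  shocks3 <- event_log(time = c(0, 90, 210, 350, 400),
                       code = c("RHYTHM", "DEFIB", "DEFIB", "DEFIB", "STATE"),
                       detail = c("cVF", "150J indicated", "150J indicated",
                                  "150J indicated", "EXIT"))
  m <- defibrillation_metrics(shocks3)
  expect_equal(m[["time_to_first_defib"]], 90)
  expect_equal(m[["n_indicated_defibs"]], 3)
  expect_equal(m[["n_non_indicated_defibs"]], 0)
  expect_equal(m[["fraction_indicated"]], 1)
  expect_equal(m[["mean_defib_interval"]], 130)  # (120 + 140) / 2
  expect_equal(m[["mean_abs_dev_from_target_interval"]], 10)  # (0 + 20) / 2

  single <- event_log(time = c(0, 7, 100),
                      code = c("RHYTHM", "DEFIB", "STATE"),
                      detail = c("cVF", "150J indicated", "EXIT"))
  m <- defibrillation_metrics(single)
  expect_equal(m[["time_to_first_defib"]], 7)
  expect_true(is.na(m[["mean_defib_interval"]]))
  expect_true(is.na(m[["mean_abs_dev_from_target_interval"]]))

  none <- event_log(time = c(0, 100), code = c("RHYTHM", "STATE"),
                    detail = c("cVF", "EXIT"))
  m <- defibrillation_metrics(none)
  expect_true(is.na(m[["time_to_first_defib"]]))
  expect_equal(m[["n_indicated_defibs"]], 0)
  expect_true(is.na(m[["fraction_indicated"]]))
})

test_that("equally spaced shocks recover spacing and |spacing - 120| exactly", {
  for (tau in c(90, 120, 150, 200)) {
    times <- seq(60, by = tau, length.out = 5)
    lg <- event_log(time = c(0, times, max(times) + 10),
                    code = c("RHYTHM", rep("DEFIB", 5), "STATE"),
                    detail = c("cVF", rep("150J indicated", 5), "EXIT"))
    m <- defibrillation_metrics(lg)
    expect_equal(m[["mean_defib_interval"]], tau)
    expect_equal(m[["mean_abs_dev_from_target_interval"]], abs(tau - 120))
  }
})

test_that("adrenaline time prefers the marker and falls back to the drug log", {
  marker <- event_log(time = c(0, 536, 600),
                      code = c("RHYTHM", "MARKER", "STATE"),
                      detail = c("cVF", "EPI_1", "EXIT"))
  t <- drug_and_marker_times(marker, drug_log())
  expect_equal(t[["time_to_first_epinephrine"]], 536)
  expect_equal(format_mmss(536), "08:56")

  bare <- event_log(time = c(0, 600), code = c("RHYTHM", "STATE"),
                    detail = c("cVF", "EXIT"))
  dl <- drug_log(time = 400, drug = "adrenaline", dose = "1 mg")
  expect_equal(drug_and_marker_times(bare, dl)[["time_to_first_epinephrine"]],
               400)
  t <- drug_and_marker_times(bare, drug_log())
  expect_true(is.na(t[["time_to_first_epinephrine"]]))
  expect_true(is.na(t[["time_to_intubation"]]))
})

test_that("ventilations count strictly before intubation", {
  lg <- event_log(time = c(0, 20, 50, 80, 110, 300, 400, 500),
                  code = c("RHYTHM", "VENT", "VENT", "VENT", "VENT",
                           "MARKER", "VENT", "STATE"),
                  detail = c("cVF", "", "", "", "", "INTUBATION", "", "EXIT"))
  vm <- ventilation_metrics(lg, t_intubation = 300, window_end = 500)
  expect_equal(vm[["n_ventilations_pre_intubation"]], 4)  # the 400 s one is out
  expect_equal(vm[["vent_frequency_pre_intubation"]], 0.8)  # 4 / 5 min

  vm <- ventilation_metrics(lg, t_intubation = NA, window_end = 500)
  expect_equal(vm[["n_ventilations_pre_intubation"]], 5)

  none <- event_log(time = c(0, 500), code = c("RHYTHM", "STATE"),
                    detail = c("cVF", "EXIT"))
  vm <- ventilation_metrics(none, NA, 500)
  expect_equal(vm[["n_ventilations_pre_intubation"]], 0)
  expect_equal(vm[["vent_frequency_pre_intubation"]], 0)
  vm <- ventilation_metrics(none, 0, 500)
  expect_true(is.na(vm[["vent_frequency_pre_intubation"]]))
})

test_that("median cardiac output is windowed with the midpoint convention", {
  mk <- function(co) physio_log(time = seq(0, by = 5,
                                           length.out = length(co)),
                                hr = 0 * co, sbp = 0 * co, dbp = 0 * co,
                                cardiac_output = co, spo2 = 0 * co)
  expect_equal(median_cardiac_output(mk(c(0, 0, 1.4, 1.6, 1.5)), 100), 1.4)
  expect_equal(median_cardiac_output(mk(1.2), 100), 1.2)
  expect_equal(median_cardiac_output(mk(c(0, 1.0, 1.4, 1.6)), 100), 1.2)
  # post-window samples are excluded
  expect_equal(median_cardiac_output(mk(c(1.5, 1.5, 5, 5)), 6), 1.5)
  expect_error(median_cardiac_output(physio_log(), 100), "no physio samples")
})

test_that("compute_metrics composes its sub-operations consistently", {
  p <- suppressWarnings(random_profile(7))
  res <- run_scenario(p, horizon = 900)
  r <- res$report
  nf <- no_flow_metrics(res$event)
  df <- defibrillation_metrics(res$event)
  expect_equal(r$no_flow_time, nf[["no_flow_time"]])
  expect_equal(r$time_to_first_defib, df[["time_to_first_defib"]])
  if (!is.na(r$fraction_indicated)) {
    expect_equal(r$fraction_indicated *
                   (r$n_indicated_defibs + r$n_non_indicated_defibs),
                 r$n_indicated_defibs)
  }
  expect_true(r$no_flow_time_fraction >= 0 && r$no_flow_time_fraction <= 1)
  expect_true(r$no_flow_time <= r$assessment_duration)
  # determinism of the whole pipeline
  expect_equal(run_scenario(p, horizon = 900)$report, r)
})

test_that("cohort summaries use mean and population SD with printed precision", {
  reps <- lapply(c(1.2, 1.5, 1.4, 1.8, 1.5), function(v) {
    metrics_report(median_cardiac_output = v)
  })
  s <- summarize_cohort(reps)
  row <- s[s$metric == "median_cardiac_output", ]
  expect_equal(row$n, 5)
  expect_equal(row$formatted, "1.5 ± 0.2")
  expect_equal(row$sd, sqrt(mean((c(1.2, 1.5, 1.4, 1.8, 1.5) - 1.48)^2)))

  same <- replicate(5, metrics_report(no_flow_time_fraction = 0.3,
                                      time_to_rosc = 700),
                    simplify = FALSE)
  s <- summarize_cohort(same)
  expect_true(all(s$sd[s$n > 0] == 0))
  one <- summarize_cohort(list(metrics_report(time_to_rosc = 728)))
  row <- one[one$metric == "time_to_rosc", ]
  expect_equal(row$mean, 728)
  expect_equal(row$sd, 0)
  expect_equal(row$formatted, "12:08 ± 00:00")
  expect_error(summarize_cohort(list()), "non-empty")
})

test_that("per-scenario reports round-trip through both file formats", {
  p <- suppressWarnings(random_profile(11))
  r <- run_scenario(p, horizon = 900)$report
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_metrics_report(r, path, fmt)
    expect_equal(read_metrics_report(path), r)
  }
  expect_error(metrics_report(bogus_field = 1), "unknown metrics_report")
})
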