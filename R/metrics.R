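#' Per-scenario performance report
#'
#' Container for the performance variables extracted from one scenario's
#' logs.  All fields are scalar numbers; `NA` marks a quantity that does not
#' exist for the scenario (no ROSC, no shocks, no adrenaline, ...).
#'
#' Fields: `median_cardiac_output` (L/min), `mean_cardiac_output` (L/min,
#' supplementary), `no_flow_time` (s), `no_flow_time_fraction` (0-1),
#' `time_to_rosc` (s), `time_to_first_epinephrine` (s),
#' `time_to_first_defib` (s), `n_indicated_defibs`,
#' `n_non_indicated_defibs`, `fraction_indicated` (0-1),
#' `mean_defib_interval` (s), `mean_abs_dev_from_target_interval` (s),
#' `n_ventilations_pre_intubation`, `vent_frequency_pre_intubation`
#' (min^-1), `assessment_duration` (s, supplementary).
#'
#' @param ... field values; unnamed fields are rejected, unknown names are
#'   rejected, omitted fields default to `NA`.
#' @return An object of class `metrics_report` (a named list).
#' @export
metrics_report <- function(...) {
  vals <- list(...)
  fields <- metrics_report_fields()
  if (length(vals) > 0 &&
      (is.null(names(vals)) || any(!nzchar(names(vals))))) {
    stop("metrics_report fields must be named", call. = FALSE)
  }
  unknown <- setdiff(names(vals), fields)
  if (length(unknown) > 0) {
    stop("unknown metrics_report field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(as.list(rep(NA_real_, length(fields))), fields)
  for (nm in names(vals)) out[[nm]] <- as.numeric(vals[[nm]])
  structure(out, class = "metrics_report")
}

metrics_report_fields <- function() {
  c("median_cardiac_output", "mean_cardiac_output",
    "no_flow_time", "no_flow_time_fraction",
    "time_to_rosc", "time_to_first_epinephrine", "time_to_first_defib",
    "n_indicated_defibs", "n_non_indicated_defibs", "fraction_indicated",
    "mean_defib_interval", "mean_abs_dev_from_target_interval",
    "n_ventilations_pre_intubation", "vent_frequency_pre_intubation",
    "assessment_duration")
}

# metric kinds drive cohort formatting and mm:ss companions
metric_kind <- c(
  median_cardiac_output = "rate", mean_cardiac_output = "rate",
  no_flow_time = "time", no_flow_time_fraction = "fraction",
  time_to_rosc = "time", time_to_first_epinephrine = "time",
  time_to_first_defib = "time",
  n_indicated_defibs = "count", n_non_indicated_defibs = "count",
  fraction_indicated = "fraction",
  mean_defib_interval = "time", mean_abs_dev_from_target_interval = "time",
  n_ventilations_pre_intubation = "count",
  vent_frequency_pre_intubation = "rate",
  assessment_duration = "time")

#' Assessment window of a scenario
#'
#' All time-fraction metrics share one denominator: the window runs from
#' scenario start (t = 0) to the ROSC event if one occurred, otherwise to
#' the last event record (a censored scenario that never converted).
#'
#' @param event_log an [event_log()].
#' @return `c(start = 0, end = <seconds>)`.
#' @export
assessment_window <- function(event_log) {
  stopifnot(inherits(event_log, "event_log"))
  if (nrow(event_log) == 0) {
    stop("cannot take an assessment window of an empty event log",
         call. = FALSE)
  }
  rosc <- event_log$time[event_log$code == "ROSC"]
  end <- if (length(rosc) > 0) rosc[[1]] else max(event_log$time)
  c(start = 0, end = end)
}

first_or_na <- function(x) if (length(x) > 0) x[[1]] else NA_real_

# compression intervals [on, off) from CC_ON/CC_OFF records; an unclosed
# segment is closed at `end`
cc_intervals <- function(event_log, end) {
  on_t <- event_log$time[event_log$code == "CC_ON"]
  off_t <- event_log$time[event_log$code == "CC_OFF"]
  if (length(off_t) > length(on_t) ||
      (length(on_t) > 0 && length(off_t) > 0 && off_t[[1]] < on_t[[1]])) {
    stop("CC_OFF without a matching CC_ON", call. = FALSE)
  }
  if (length(on_t) > length(off_t)) off_t <- c(off_t, end)
  cbind(on = on_t, off = off_t)
}

#' No-flow time and no-flow-time fraction
#'
#' No-flow time is the cumulative time within the assessment window during
#' which the arrested patient receives no chest compressions (no forward
#' blood flow); the fraction divides by the window length (it is the
#' complement of the chest-compression fraction).  Time after ROSC does not
#' count: the window ends there.
#'
#' @param event_log an [event_log()] containing `CC_ON`/`CC_OFF` records.
#' @return `c(no_flow_time = <s>, no_flow_time_fraction = <0-1>)`.
#' @export
no_flow_metrics <- function(event_log) {
  window <- assessment_window(event_log)
  end <- window[["end"]]
  iv <- cc_intervals(event_log, end)
  flow <- 0
  if (nrow(iv) > 0) {
    on <- pmin(pmax(iv[, "on"], 0), end)
    off <- pmin(pmax(iv[, "off"], 0), end)
    flow <- sum(pmax(off - on, 0))
  }
  nft <- max(end - flow, 0)
  c(no_flow_time = nft,
    no_flow_time_fraction = if (end > 0) nft / end else NA_real_)
}

#' Defibrillation timing and classification metrics
#'
#' Works over the shocks recorded within the assessment window.  The mean
#' interval over n >= 2 shocks is the mean of consecutive differences
#' (equivalently `(t_last - t_first) / (n - 1)`); the mean absolute
#' deviation compares each interval with the guideline target cycle
#' (default 120 s).  With fewer than two shocks both are `NA`; with no
#' shocks the first-shock time and indicated fraction are `NA` and the
#' counts zero.
#'
#' @param event_log an [event_log()].
#' @param cfg a [guideline_config()].
#' @return A named numeric vector: `time_to_first_defib`,
#'   `n_indicated_defibs`, `n_non_indicated_defibs`, `fraction_indicated`,
#'   `mean_defib_interval`, `mean_abs_dev_from_target_interval`.
#' @export
defibrillation_metrics <- function(event_log, cfg = guideline_config()) {
  window <- assessment_window(event_log)
  keep <- event_log$code == "DEFIB" & event_log$time <= window[["end"]]
  times <- event_log$time[keep]
  cls <- vapply(event_log$detail[keep],
                function(d) parse_defib_detail(d)$classification,
                character(1), USE.NAMES = FALSE)
  n_ind <- sum(cls == "indicated")
  n_non <- sum(cls == "non_indicated")
  n <- n_ind + n_non
  intervals <- if (n >= 2) diff(times) else numeric(0)
  c(time_to_first_defib = first_or_na(times),
    n_indicated_defibs = n_ind,
    n_non_indicated_defibs = n_non,
    fraction_indicated = if (n > 0) n_ind / n else NA_real_,
    mean_defib_interval = if (n >= 2) mean(intervals) else NA_real_,
    mean_abs_dev_from_target_interval =
      if (n >= 2) mean(abs(intervals - cfg$target_shock_interval))
      else NA_real_)
}

#' First-adrenaline and intubation times
#'
#' The first-adrenaline time is the earliest first-adrenaline marker
#' (`EPI_1`); when the marker was never clicked, the earliest adrenaline
#' record of the drug log is used as fallback.  The intubation time is the
#' earliest intubation marker.  `NA` when absent.
#'
#' @param event_log an [event_log()].
#' @param drug_log a [drug_log()].
#' @return `c(time_to_first_epinephrine = <s|NA>, time_to_intubation = <s|NA>)`.
#' @export
drug_and_marker_times <- function(event_log, drug_log) {
  stopifnot(inherits(event_log, "event_log"), inherits(drug_log, "drug_log"))
  epi_marker <- event_log$time[event_log$code == "MARKER" &
                                 event_log$detail == "EPI_1"]
  t_epi <- if (length(epi_marker) > 0) {
    min(epi_marker)
  } else {
    adren <- drug_log$time[drug_log$drug == "adrenaline"]
    if (length(adren) > 0) min(adren) else NA_real_
  }
  intub <- event_log$time[event_log$code == "MARKER" &
                            event_log$detail == "INTUBATION"]
  c(time_to_first_epinephrine = t_epi,
    time_to_intubation = if (length(intub) > 0) min(intub) else NA_real_)
}

#' Pre-intubation ventilation count and frequency
#'
#' After intubation compressions continue without interruption and the
#' original log stream cannot attribute ventilations reliably, so only the
#' period before intubation is assessed.  The count is the number of `VENT`
#' events strictly before the intubation time (before the window end when
#' the patient was never intubated); the frequency divides by that
#' denominator in minutes.
#'
#' @param event_log an [event_log()].
#' @param t_intubation intubation time in seconds, or `NA`.
#' @param window_end assessment window end in seconds.
#' @return `c(n_ventilations_pre_intubation = <count>,
#'   vent_frequency_pre_intubation = <min^-1>)`.
#' @export
ventilation_metrics <- function(event_log, t_intubation, window_end) {
  stopifnot(inherits(event_log, "event_log"))
  cutoff <- if (is.na(t_intubation)) window_end else t_intubation
  count <- sum(event_log$code == "VENT" & event_log$time < cutoff)
  freq <- if (cutoff <= 0) NA_real_ else count / (cutoff / 60)
  c(n_ventilations_pre_intubation = count,
    vent_frequency_pre_intubation = freq)
}

#' Median (and mean) cardiac output over the assessment window
#'
#' Order statistic over the physio-log cardiac-output samples with time at
#' or before the window end; the sample convention places a sample taken at
#' the ROSC instant on the pre-ROSC side, so post-ROSC plateau values never
#' enter.  Even sample counts use the usual midpoint convention.
#'
#' @param physio_log a [physio_log()].
#' @param window_end seconds.
#' @return Median cardiac output in L/min.
#' @export
median_cardiac_output <- function(physio_log, window_end) {
  stopifnot(inherits(physio_log, "physio_log"))
  co <- physio_log$cardiac_output[physio_log$time <= window_end]
  if (length(co) == 0) {
    stop("no physio samples inside the assessment window", call. = FALSE)
  }
  stats::median(co)
}

#' Extract the full performance report from a scenario's logs
#'
#' Assembles every per-scenario performance variable: median (and mean)
#' cardiac output, no-flow time and fraction, time to ROSC, time to first
#' adrenaline, defibrillation timing/classification metrics and
#' pre-intubation ventilation metrics.  The report is a pure function of
#' the three logs.
#'
#' @param event_log,physio_log,drug_log the three logs of one scenario.
#' @param cfg a [guideline_config()].
#' @return A [metrics_report()].
#' @examples
#' logs <- run_engine(action_stream(), "cVF", horizon = 300)
#' rep <- compute_metrics(logs$event, logs$physio, logs$drug)
#' rep$no_flow_time_fraction  # 1: nobody touched the patient
#' @export
compute_metrics <- function(event_log, physio_log, drug_log,
                            cfg = guideline_config()) {
  window <- assessment_window(event_log)
  end <- window[["end"]]
  nf <- no_flow_metrics(event_log)
  df <- defibrillation_metrics(event_log, cfg)
  dm <- drug_and_marker_times(event_log, drug_log)
  vm <- ventilation_metrics(event_log, dm[["time_to_intubation"]], end)
  co <- physio_log$cardiac_output[physio_log$time <= end]
  rosc <- first_or_na(event_log$time[event_log$code == "ROSC"])
  metrics_report(
    median_cardiac_output = median_cardiac_output(physio_log, end),
    mean_cardiac_output = mean(co),
    no_flow_time = nf[["no_flow_time"]],
    no_flow_time_fraction = nf[["no_flow_time_fraction"]],
    time_to_rosc = rosc,
    time_to_first_epinephrine = dm[["time_to_first_epinephrine"]],
    time_to_first_defib = df[["time_to_first_defib"]],
    n_indicated_defibs = df[["n_indicated_defibs"]],
    n_non_indicated_defibs = df[["n_non_indicated_defibs"]],
    fraction_indicated = df[["fraction_indicated"]],
    mean_defib_interval = df[["mean_defib_interval"]],
    mean_abs_dev_from_target_interval =
      df[["mean_abs_dev_from_target_interval"]],
    n_ventilations_pre_intubation = vm[["n_ventilations_pre_intubation"]],
    vent_frequency_pre_intubation = vm[["vent_frequency_pre_intubation"]],
    assessment_duration = end)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    shown <- if (is.na(v)) "NA"
    else if (metric_kind[[nm]] == "time") {
      paste0(format_mmss(v), " (", format(round(v), trim = TRUE), " s)")
    } else format(round(v, 3), trim = TRUE)
    cat(sprintf("  %-34s %s\n", nm, shown))
  }
  invisible(x)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Cohort summary (mean and population SD per metric)
#'
#' Aggregates a list of per-scenario reports into one row per metric with
#' the available-case count, mean and population standard deviation
#' (divisor n).  `NA` fields are excluded metric-wise.  The `formatted`
#' column renders each cell at the report's printed precision: times as
#' `MM:SS`, fractions to two decimals, counts and rates to one decimal.
#'
#' @param reports a non-empty list of [metrics_report()] objects.
#' @return A `data.frame` of class `cohort_summary` with columns `metric`,
#'   `n`, `mean`, `sd`, `formatted`.
#' @examples
#' reps <- lapply(c(1.2, 1.5, 1.4, 1.8, 1.5),
#'                function(v) metrics_report(median_cardiac_output = v))
#' summarize_cohort(reps)[1, ]
#' @export
summarize_cohort <- function(reports) {
  if (!is.list(reports) || length(reports) == 0 ||
      !all(vapply(reports, inherits, logical(1), "metrics_report"))) {
    stop("reports must be a non-empty list of metrics_report objects",
         call. = FALSE)
  }
  fields <- metrics_report_fields()
  rows <- lapply(fields, function(nm) {
    x <- vapply(reports, function(r) r[[nm]], numeric(1))
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n > 0) mean(x) else NA_real_
    s <- if (n > 0) pop_sd(x) else NA_real_
    data.frame(metric = nm, n = n, mean = m, sd = s,
               formatted = format_summary_cell(nm, m, s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

format_summary_cell <- function(metric, m, s) {
  if (is.na(m)) return(NA_character_)
  kind <- metric_kind[[metric]]
  switch(kind,
    time = paste0(format_mmss(m), " ± ", format_mmss(s)),
    fraction = sprintf("%.2f ± %.2f", m, s),
    sprintf("%.1f ± %.1f", m, s))
}

#' Read or write a per-scenario report file
#'
#' The flat TSV form holds one `field<TAB>value` line per metric (raw
#' value; `NA` for absent quantities) plus a `<field>_mmss` companion line
#' for every non-`NA` time metric.  The JSON form mirrors the same fields.
#' Reading a written report reproduces it.
#'
#' @param report a [metrics_report()].
#' @param path destination file.
#' @param format `"tsv"` or `"json"`; `read_metrics_report` infers it from
#'   the file extension.
#' @return `write_metrics_report` returns `path` invisibly;
#'   `read_metrics_report` returns a [metrics_report()].
#' @export
write_metrics_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "metrics_report"))
  format <- match.arg(format)
  vals <- unclass(report)
  mmss <- list()
  for (nm in names(vals)) {
    if (metric_kind[[nm]] == "time" && !is.na(vals[[nm]])) {
      mmss[[paste0(nm, "_mmss")]] <- format_mmss(vals[[nm]])
    }
  }
  if (format == "tsv") {
    write_kv_file(c(vals, mmss), path)
  } else {
    jsonlite::write_json(c(vals, mmss), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  fields <- metrics_report_fields()
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    jsonlite::read_json(path)
  } else {
    read_kv_file(path)
  }
  vals <- vals[intersect(names(vals), fields)]
  vals <- lapply(vals, function(v) {
    if (is.null(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
  })
  do.call(metrics_report, vals)
}

#' Write a cohort summary table
#'
#' @param summary a [summarize_cohort()] result.
#' @param path destination file.
#' @param format `"tsv"` (tab-separated table) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path, format = c("tsv", "json")) {
  stopifnot(inherits(summary, "cohort_summary"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(summary, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(as.data.frame(summary), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
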