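# scenario engine: hand-traced replays, state sequencing, determinism

test_that("an untouched cVF patient degenerates at the timeout and never flows", {
  logs <- run_engine(action_stream(), "cVF", horizon = 600)
  ev <- logs$event
  expect_identical(ev$code, c("STATE", "RHYTHM", "RHYTHM", "STATE"))
  expect_identical(ev$detail, c("NO_CC", "cVF", "ASY", "EXIT"))
  expect_equal(ev$time, c(0, 0, 60, 600))
  expect_true(all(logs$physio$cardiac_output == 0))
  expect_equal(nrow(logs$physio), 121)  # 5 s sampling over 600 s inclusive
  expect_equal(nrow(logs$drug), 0)
})

test_that("compressions alone enter CC, perfuse, and prevent degeneration", {
  acts <- action_stream(10, "cc_start")
  logs <- run_engine(acts, "cVF", horizon = 300, profile_cc_output = 1.5)
  ev <- logs$event
  expect_true(any(ev$code == "STATE" & ev$detail == "CC" & ev$time == 10))
  expect_false(any(ev$code == "RHYTHM" & ev$detail == "ASY"))
  co <- logs$physio
  expect_true(all(co$cardiac_output[co$time > 10] == 1.5))
  expect_true(all(co$cardiac_output[co$time <= 10] == 0))
})

test_that("the engine is a pure function of its inputs", {
  p <- suppressWarnings(random_profile(42))
  acts <- generate_actions(p, 900)
  a <- run_engine(acts, "cVF", profile_cc_output = p$cc_output, horizon = 900)
  b <- run_engine(acts, "cVF", profile_cc_output = p$cc_output, horizon = 900)
  expect_identical(a, b)
})

test_that("every recorded shock enters exactly one classification state", {
  for (seed in 1:5) {
    p <- suppressWarnings(random_profile(seed))
    acts <- generate_actions(p, 900)
    # mix in ignored and over-cap energies
    set.seed(seed + 1000)
    is_defib <- which(acts$kind == "defibrillation")
    acts$energy[is_defib] <- sample(c(5, 10, 150, 250), length(is_defib),
                                    replace = TRUE)
    logs <- run_engine(acts, "cVF", profile_cc_output = p$cc_output,
                       horizon = 900)
    ev <- logs$event
    n_cls <- sum(ev$code == "STATE" &
                   ev$detail %in% c("DEFIB_INDICATED", "DEFIB_NON_INDICATED"))
    expect_equal(n_cls, sum(acts$energy[is_defib] > 10))
    expect_equal(sum(ev$code == "DEFIB"), n_cls)
  }
})

test_that("ignored shocks leave no trace and over-cap shocks are flagged", {
  acts <- action_stream(c(50, 100), "defibrillation", energy = c(10, 250))
  logs <- run_engine(acts, "cVF", horizon = 120)
  ev <- logs$event
  expect_equal(sum(ev$code == "DEFIB"), 1)
  expect_equal(ev$time[ev$code == "DEFIB"], 100)
  warn <- ev[ev$code == "WARN", ]
  expect_equal(nrow(warn), 1)
  expect_match(warn$detail, "250J")
})

test_that("markers pass through their state, return to NO_CC and feed the drug log", {
  acts <- action_stream(c(5, 30, 40), c("cc_start", "marker", "marker"),
                        marker = c(NA, "EPI_1", "ATROPINE"))
  logs <- run_engine(acts, "cVF", horizon = 120)
  ev <- logs$event
  at30 <- ev[ev$time == 30 & ev$code == "STATE", "detail"]
  expect_identical(at30, c("MARKER_EPI_1", "NO_CC", "CC"))
  expect_identical(logs$drug$drug, c("adrenaline", "atropine"))
  expect_identical(logs$drug$dose, c("1 mg", "3 mg"))
  expect_equal(logs$drug$time, c(30, 40))
})

test_that("the drug-compression-shock chain produces ROSC and the post-ROSC plateau", {
  acts <- action_stream(
    c(5, 60, 120, 130, 200),
    c("cc_start", "defibrillation", "marker", "cc_start", "defibrillation"),
    energy = c(NA, 150, NA, NA, 150),
    marker = c(NA, NA, "EPI_2", NA, NA))
  # cc runs 5..115 then resumes at 130 (the cc_start at 130 re-arms cf_lv)
  acts <- rbind(acts[1:2, ], action_stream(115, "cc_stop"), acts[3:5, ])
  acts <- validate_action_stream(acts[order(acts$time), ])
  logs <- run_engine(acts, "cVF", horizon = 300)
  ev <- logs$event
  # shock before arming is recorded indicated but does not convert
  expect_equal(ev$time[ev$code == "DEFIB"], c(60, 200))
  expect_equal(ev$time[ev$code == "ROSC"], 200)
  expect_true(any(ev$code == "RHYTHM" & ev$detail == "SR" & ev$time == 200))
  post <- logs$physio[logs$physio$time > 200, ]
  expect_true(all(post$cardiac_output == 5.0))
  expect_true(all(post$sbp == 120))
})

test_that("without compressions failure is absorbing: ASY, and no shock ever converts", {
  acts <- action_stream(c(100, 200, 400), "defibrillation",
                        energy = c(150, 150, 150))
  logs <- run_engine(acts, "cVF", horizon = 600)
  ev <- logs$event
  expect_true(any(ev$code == "RHYTHM" & ev$detail == "ASY" & ev$time == 60))
  expect_false(any(ev$code == "ROSC"))
  cls <- ev$detail[ev$code == "DEFIB"]
  expect_true(all(grepl("non_indicated", cls)))
})

test_that("unsorted or malformed action streams are rejected", {
  bad <- data.frame(time = c(10, 5), kind = c("cc_start", "cc_stop"))
  expect_error(run_engine(bad, "cVF"), "sorted")
  expect_error(action_stream(5, "jump"), "unknown action kind")
  expect_error(action_stream(5, "defibrillation"), "energy")
  expect_error(action_stream(5, "marker"), "marker")
  expect_error(action_stream(5, "cc_start", energy = 100), "only valid")
})

test_that("scenario_transition follows the SBP gate and state sequences", {
  cfg <- guideline_config()
  p <- initialize_patient("cVF")
  sc <- scenario_state("NO_CC", 0)
  ev <- function(t, kind, energy = NA, marker = NA) {
    action_stream(t, kind, energy = energy, marker = marker)
  }
  p$sbp <- 60
  expect_identical(scenario_transition(sc, p, ev(10, "cc_start"), cfg), "CC")
  p$sbp <- 40  # the gate is strictly "superior to 40"
  expect_identical(scenario_transition(sc, p, ev(10, "cc_start"), cfg),
                   "INEFFECTIVE_RESUSCITATION")
  p$sbp <- 0
  expect_identical(
    scenario_transition(sc, p, ev(10, "marker", marker = "EPI_1"), cfg),
    c("MARKER_EPI_1", "NO_CC"))
  expect_identical(
    scenario_transition(sc, p, ev(10, "defibrillation", energy = 150), cfg),
    c("DEFIB", "DEFIB_INDICATED", "NO_CC"))
  expect_identical(
    scenario_transition(sc, p, ev(10, "defibrillation", energy = 5), cfg),
    character(0))
  in_cc <- scenario_state("CC", 0)
  expect_identical(scenario_transition(in_cc, p, ev(10, "ventilation"), cfg),
                   c("VENTILATION", "CC"))
  expect_error(
    scenario_transition(scenario_state("CC", 50), p, ev(10, "ventilation"),
                        cfg),
    "out-of-order")
})
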