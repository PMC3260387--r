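# Independent brute-force oracle: replays an action stream second by second
# with its own bookkeeping (no engine code, no interval arithmetic) and
# returns the quantities the metrics layer should report.  Deliberately
# naive so it stays a cross-check, not a re-export of the implementation.
oracle_scan <- function(actions, initial_rhythm, horizon,
                        sample_interval = 5, cc_output = 1.5,
                        floor = 10, timeout = 60, target = 120,
                        rosc_co = 5.0) {
  rhythm <- initial_rhythm
  armed <- FALSE
  cf08 <- FALSE
  cc <- FALSE
  last_stop <- 0
  rosc <- NA_real_
  shock_t <- numeric(0)
  shock_cls <- character(0)
  co_t <- numeric(0)
  co_v <- numeric(0)
  cc_sec <- logical(horizon)

  by_sec <- split(seq_len(nrow(actions)), actions$time)

  for (s in 0:horizon) {
    if (s %% sample_interval == 0) {
      co_t <- c(co_t, s)
      co_v <- c(co_v, if (rhythm == "SR") rosc_co
                      else if (cc) cc_output else 0)
    }
    idx <- by_sec[[as.character(s)]]
    for (k in idx) {
      kind <- actions$kind[[k]]
      if (kind == "cc_start") {
        cc <- TRUE
      } else if (kind == "cc_stop") {
        if (cc) { cc <- FALSE; last_stop <- s }
      } else if (kind == "marker") {
        if (actions$marker[[k]] %in% c("EPI_2", "AMIODARONE")) armed <- TRUE
      } else if (kind == "defibrillation") {
        e <- actions$energy[[k]]
        if (e > floor) {
          cls <- if (rhythm %in% c("cVF", "pVT")) "indicated"
                 else "non_indicated"
          shock_t <- c(shock_t, s)
          shock_cls <- c(shock_cls, cls)
          if (cls == "indicated" && cf08 && is.na(rosc)) {
            rhythm <- "SR"
            rosc <- s
          }
        }
      }
      if (armed && cc) cf08 <- TRUE
    }
    if (!cc && rhythm %in% c("cVF", "pVT") && (s - last_stop) >= timeout) {
      rhythm <- "ASY"
    }
    if (s < horizon) cc_sec[[s + 1]] <- cc
  }

  end <- if (is.na(rosc)) horizon else rosc
  flow <- if (end > 0) sum(cc_sec[seq_len(end)]) else 0
  keep <- shock_t <= end
  st <- shock_t[keep]
  sc <- shock_cls[keep]
  n <- length(st)
  list(
    window_end = end,
    time_to_rosc = rosc,
    no_flow_time = end - flow,
    no_flow_time_fraction = if (end > 0) (end - flow) / end else NA_real_,
    time_to_first_defib = if (n > 0) st[[1]] else NA_real_,
    n_indicated_defibs = sum(sc == "indicated"),
    n_non_indicated_defibs = sum(sc == "non_indicated"),
    mean_defib_interval = if (n >= 2) mean(diff(st)) else NA_real_,
    mean_abs_dev_from_target_interval =
      if (n >= 2) mean(abs(diff(st) - target)) else NA_real_,
    median_cardiac_output = stats::median(co_v[co_t <= end])
  )
}

# random but reproducible team profile spanning the generator's range,
# including teams that never arm the drug chain, never ventilate, or pause
# long enough to degenerate to asystole
random_profile <- function(seed) {
  set.seed(seed)
  maybe_na <- function(v, p = 0.35) if (stats::runif(1) < p) NA else v
  team_profile(
    t_first_defib_mean = stats::runif(1, 20, 250),
    t_first_defib_sd = stats::runif(1, 0, 30),
    shock_interval_mean = stats::runif(1, 90, 260),
    shock_interval_sd = stats::runif(1, 0, 35),
    peri_shock_pause = sample(0:20, 1),
    cc_segment_mean = stats::runif(1, 15, 120),
    cc_segment_sd = stats::runif(1, 0, 15),
    cc_pause_mean = stats::runif(1, 2, 80),
    cc_pause_sd = stats::runif(1, 0, 15),
    vent_rate = stats::runif(1, 0, 6),
    t_iv = maybe_na(round(stats::runif(1, 30, 400))),
    t_intubation = maybe_na(round(stats::runif(1, 60, 600))),
    t_epi1 = maybe_na(round(stats::runif(1, 100, 700))),
    t_epi2 = maybe_na(round(stats::runif(1, 150, 1000))),
    t_amiodarone = maybe_na(round(stats::runif(1, 150, 1000)), p = 0.6),
    t_atropine = maybe_na(round(stats::runif(1, 100, 800)), p = 0.8),
    cc_output = round(stats::runif(1, 0.8, 2.5), 1),
    seed = seed
  )
}

# deterministic profile with no drug markers: never converts, so the full
# horizon is the assessment window
no_drug_profile <- function(...) {
  team_profile(t_iv = NA, t_intubation = NA, t_epi1 = NA, t_epi2 = NA,
               t_amiodarone = NA, t_atropine = NA, ...)
}
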