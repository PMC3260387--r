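#' Rescuer-team behavior profile
#'
#' Parameterises the synthetic generator that emulates a resuscitation
#' team's action stream: alternating chest-compression segments and pauses,
#' shocks spaced around a team-typical interval with a peri-shock pause
#' carved out of the compressions (rescuers clear the patient), bag-mask
#' ventilations until intubation, and the observer-clicked marker times
#' (IV line, intubation, adrenaline doses, optional amiodarone/atropine).
#' Interval and segment draws are left-censored normals (censored at the
#' stated lower bounds), so `sd = 0` profiles are exactly deterministic —
#' the basis of the parameter-recovery properties.
#'
#' @param t_first_defib_mean,t_first_defib_sd time of first shock, s.
#' @param shock_interval_mean,shock_interval_sd spacing of subsequent
#'   shocks, s.
#' @param peri_shock_pause compression pause carved out around each shock,
#'   s (split half before, half after).
#' @param cc_segment_mean,cc_segment_sd compression segment length, s.
#' @param cc_pause_mean,cc_pause_sd pause between segments, s.
#' @param vent_rate pre-intubation ventilation rate, min^-1 (0 disables).
#' @param t_iv,t_intubation,t_epi1,t_epi2 marker times, s (`NA` omits).
#' @param t_amiodarone,t_atropine optional marker times, s or `NA`.
#' @param cc_output cardiac output generated by this team's compressions,
#'   L/min, in (0, 3].
#' @param seed integer RNG seed for the draws.
#' @return An object of class `team_profile` (a named list).
#' @export
team_profile <- function(t_first_defib_mean = 90, t_first_defib_sd = 0,
                         shock_interval_mean = 120, shock_interval_sd = 0,
                         peri_shock_pause = 10,
                         cc_segment_mean = 60, cc_segment_sd = 0,
                         cc_pause_mean = 8, cc_pause_sd = 0,
                         vent_rate = 1,
                         t_iv = 120, t_intubation = 240,
                         t_epi1 = 180, t_epi2 = 300,
                         t_amiodarone = NA, t_atropine = NA,
                         cc_output = 1.5, seed = 1L) {
  p <- list(t_first_defib_mean = as.numeric(t_first_defib_mean),
            t_first_defib_sd = as.numeric(t_first_defib_sd),
            shock_interval_mean = as.numeric(shock_interval_mean),
            shock_interval_sd = as.numeric(shock_interval_sd),
            peri_shock_pause = as.numeric(peri_shock_pause),
            cc_segment_mean = as.numeric(cc_segment_mean),
            cc_segment_sd = as.numeric(cc_segment_sd),
            cc_pause_mean = as.numeric(cc_pause_mean),
            cc_pause_sd = as.numeric(cc_pause_sd),
            vent_rate = as.numeric(vent_rate),
            t_iv = as.numeric(t_iv),
            t_intubation = as.numeric(t_intubation),
            t_epi1 = as.numeric(t_epi1),
            t_epi2 = as.numeric(t_epi2),
            t_amiodarone = as.numeric(t_amiodarone),
            t_atropine = as.numeric(t_atropine),
            cc_output = as.numeric(cc_output),
            seed = as.integer(seed))
  sds <- c("t_first_defib_sd", "shock_interval_sd", "cc_segment_sd",
           "cc_pause_sd")
  if (any(unlist(p[sds]) < 0)) {
    stop("team_profile: standard deviations must be >= 0", call. = FALSE)
  }
  times <- c("t_first_defib_mean", "shock_interval_mean", "peri_shock_pause",
             "cc_segment_mean", "cc_pause_mean", "t_iv", "t_intubation",
             "t_epi1", "t_epi2", "t_amiodarone", "t_atropine")
  for (nm in times) {
    if (!is.na(p[[nm]]) && p[[nm]] < 0) {
      stop("team_profile: '", nm, "' must be >= 0", call. = FALSE)
    }
  }
  if (p$vent_rate < 0) {
    stop("team_profile: vent_rate must be >= 0", call. = FALSE)
  }
  if (!(p$cc_output > 0 && p$cc_output <= 3)) {
    stop("team_profile: cc_output must lie in (0, 3] L/min", call. = FALSE)
  }
  if (!is.na(p$t_epi1) && !is.na(p$t_epi2) && p$t_epi2 < p$t_epi1) {
    warning("team_profile: second adrenaline precedes the first",
            call. = FALSE)
  }
  structure(p, class = "team_profile")
}

#' Read or write a team profile as a flat key-value file
#'
#' Same `key<TAB>value` format as [read_guideline_config()]; `NA` encodes an
#' omitted marker.
#'
#' @param path file path.
#' @param profile a [team_profile()].
#' @return `read_team_profile` returns a `team_profile`;
#'   `write_team_profile` returns `path` invisibly.
#' @export
read_team_profile <- function(path) {
  kv <- read_kv_file(path)
  known <- names(formals(team_profile))
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0) {
    stop("unknown team_profile key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(team_profile, lapply(kv, function(v) {
    suppressWarnings(if (identical(v, "NA")) NA_real_ else as.numeric(v))
  }))
}

#' @rdname read_team_profile
#' @export
write_team_profile <- function(profile, path) {
  stopifnot(inherits(profile, "team_profile"))
  write_kv_file(unclass(profile), path)
}

# left-censored normal draw; exact mean at sd = 0
draw_lcnorm <- function(mean, sd, lo = 0) {
  max(lo, stats::rnorm(1, mean, sd))
}

#' Generate a synthetic team action stream
#'
#' Builds, reproducibly under the profile seed, a full trainee action
#' stream over the scenario horizon: a per-second compression mask from
#' alternating segment/pause draws (compressions begin at t = 0) with the
#' peri-shock pause carved out around each shock, shocks (150 J) starting
#' around the first-shock time and spaced around the shock interval,
#' evenly spaced ventilations from t = 0 until intubation, and one marker
#' event per non-`NA` profile marker time.  Simultaneous events are ordered
#' compressions, then markers, then ventilations, then shocks.
#'
#' @param profile a [team_profile()].
#' @param horizon scenario length, s (> 0).
#' @param shock_energy delivered energy per shock, joules.
#' @return An [action_stream()].
#' @examples
#' p <- team_profile(t_first_defib_mean = 100, shock_interval_mean = 120,
#'                   seed = 7)
#' acts <- generate_actions(p, horizon = 600)
#' acts[acts$kind == "defibrillation", "time"]  # 100, 220, 340, 460, 580
#' @export
generate_actions <- function(profile, horizon, shock_energy = 150) {
  stopifnot(inherits(profile, "team_profile"),
            is.numeric(horizon), horizon > 0)
  horizon <- as.integer(round(horizon))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(profile$seed)

  # shock schedule
  shocks <- numeric(0)
  t <- draw_lcnorm(profile$t_first_defib_mean, profile$t_first_defib_sd, 1)
  while (t <= horizon) {
    shocks <- c(shocks, round(t))
    t <- t + draw_lcnorm(profile$shock_interval_mean,
                         profile$shock_interval_sd, 1)
  }

  # compression mask: second s covers [s, s+1); a zero-mean segment profile
  # models a team that never compresses
  mask <- logical(horizon)
  pos <- 0
  while (pos < horizon) {
    len <- round(draw_lcnorm(profile$cc_segment_mean,
                             profile$cc_segment_sd, 0))
    upper <- min(pos + len, horizon)
    if (upper > pos) mask[(pos + 1):upper] <- TRUE  # seconds pos..upper-1
    pause <- round(draw_lcnorm(profile$cc_pause_mean, profile$cc_pause_sd, 0))
    if (len + pause == 0) break
    pos <- pos + len + pause
  }
  # peri-shock clearance
  half_pre <- floor(profile$peri_shock_pause / 2)
  half_post <- ceiling(profile$peri_shock_pause / 2)
  for (ts in shocks) {
    lo <- max(ts - half_pre, 0)
    hi <- min(ts + half_post, horizon)
    if (hi > lo) mask[(lo + 1):hi] <- FALSE
  }
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths  # 0-based second of run start
  cc_on <- starts[runs$values]
  cc_off <- ends[runs$values]

  # ventilations until intubation (or horizon)
  vents <- numeric(0)
  if (profile$vent_rate > 0) {
    cutoff <- if (is.na(profile$t_intubation)) horizon
              else min(profile$t_intubation, horizon)
    if (cutoff > 0) {
      spacing <- 60 / profile$vent_rate
      vents <- unique(round(seq(0, cutoff - 1e-9, by = spacing)))
      vents <- vents[vents < cutoff]
    }
  }

  marker_times <- c(IV_LINE = profile$t_iv, INTUBATION = profile$t_intubation,
                    EPI_1 = profile$t_epi1, EPI_2 = profile$t_epi2,
                    AMIODARONE = profile$t_amiodarone,
                    ATROPINE = profile$t_atropine)
  marker_times <- marker_times[!is.na(marker_times) &
                                 marker_times <= horizon]

  rows <- rbind(
    if (length(cc_on) > 0)
      data.frame(time = cc_on, kind = "cc_start", energy = NA_real_,
                 marker = NA_character_, prio = 1,
                 stringsAsFactors = FALSE),
    if (length(cc_off) > 0)
      data.frame(time = cc_off, kind = "cc_stop", energy = NA_real_,
                 marker = NA_character_, prio = 1,
                 stringsAsFactors = FALSE),
    if (length(marker_times) > 0)
      data.frame(time = as.numeric(marker_times), kind = "marker",
                 energy = NA_real_, marker = names(marker_times), prio = 2,
                 stringsAsFactors = FALSE),
    if (length(vents) > 0)
      data.frame(time = vents, kind = "ventilation", energy = NA_real_,
                 marker = NA_character_, prio = 3,
                 stringsAsFactors = FALSE),
    if (length(shocks) > 0)
      data.frame(time = shocks, kind = "defibrillation",
                 energy = shock_energy, marker = NA_character_, prio = 4,
                 stringsAsFactors = FALSE)
  )
  if (is.null(rows)) return(action_stream())
  rows <- rows[order(rows$time, rows$prio, method = "radix"), , drop = FALSE]
  rows$prio <- NULL
  rownames(rows) <- NULL
  validate_action_stream(rows)
}

#' Run one synthetic scenario end to end
#'
#' Generates the team's action stream, replays it through the scenario
#' engine, and extracts the performance report — the full pipeline in one
#' call.  When the profile performs second adrenaline (or amiodarone)
#' followed by compressions before a later shock, the scenario reaches
#' ROSC at that shock; a profile that never arms the drug chain never
#' converts.
#'
#' @param profile a [team_profile()].
#' @param initial_rhythm `"ASY"`, `"cVF"` or `"pVT"`.
#' @param cfg a [guideline_config()].
#' @param horizon scenario length, s.
#' @param physio_sample_interval seconds between physio samples.
#' @param seed optional seed overriding `profile$seed`.
#' @return A list with components `event`, `physio`, `drug` (the logs),
#'   `report` (a [metrics_report()]) and `actions` (the generated stream).
#' @export
run_scenario <- function(profile, initial_rhythm = "cVF",
                         cfg = guideline_config(), horizon = 1200,
                         physio_sample_interval = 5, seed = NULL) {
  stopifnot(inherits(profile, "team_profile"))
  if (!is.null(seed)) profile$seed <- as.integer(seed)
  actions <- generate_actions(profile, horizon)
  logs <- run_engine(actions, initial_rhythm, cfg,
                     profile_cc_output = profile$cc_output,
                     physio_sample_interval = physio_sample_interval,
                     horizon = horizon)
  report <- compute_metrics(logs$event, logs$physio, logs$drug, cfg)
  c(logs, list(report = report, actions = actions))
}

#' The shipped fixture cohort of five team profiles
#'
#' Five behavior profiles spanning the plausible range of professional
#' teams — slow versus fast defibrillation cycles, tight versus ragged
#' compression coverage, sparse versus frequent ventilation — tuned to
#' realistic orders of magnitude only, not fitted to any particular team.
#' Shipped as flat key-value files under `inst/extdata/profiles/`.
#'
#' @return A named list of five [team_profile()] objects.
#' @export
cohort_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "cprsim")
  paths <- list.files(dir, pattern = "\\.cfg$", full.names = TRUE)
  if (length(paths) == 0) {
    stop("no fixture profiles found; is the package installed?",
         call. = FALSE)
  }
  out <- lapply(paths, read_team_profile)
  names(out) <- sub("\\.cfg$", "", basename(paths))
  out
}
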