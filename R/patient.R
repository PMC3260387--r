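#' Cardiac rhythm, marker and scenario-state vocabularies
#'
#' `rhythm_levels` enumerates the four rhythms the scenario distinguishes:
#' asystole (`ASY`), coarse ventricular fibrillation (`cVF`), pulseless
#' ventricular tachycardia (`pVT`) and sinus rhythm (`SR`).  `cVF` and `pVT`
#' (`shockable_rhythms`) are the two rhythms for which a defibrillation is
#' indicated.  `marker_levels` lists the six observer-clicked marker states
#' for actions the simulator cannot sense.  `scenario_state_levels` lists
#' every state of the scenario machine.
#'
#' @format Character vectors.
#' @export
rhythm_levels <- c("ASY", "cVF", "pVT", "SR")

#' @rdname rhythm_levels
#' @export
shockable_rhythms <- c("cVF", "pVT")

#' @rdname rhythm_levels
#' @export
marker_levels <- c("IV_LINE", "INTUBATION", "EPI_1", "EPI_2",
                   "ATROPINE", "AMIODARONE")

#' @rdname rhythm_levels
#' @export
scenario_state_levels <- c(
  "NO_CC", "CC", "VENTILATION", "INEFFECTIVE_RESUSCITATION",
  "DEFIB", "DEFIB_INDICATED", "DEFIB_NON_INDICATED",
  paste0("MARKER_", c("IV_LINE", "INTUBATION", "EPI_1", "EPI_2",
                      "ATROPINE", "AMIODARONE")),
  "EXIT"
)

# markers that also produce a drug-log record
drug_marker_map <- c(EPI_1 = "adrenaline", EPI_2 = "adrenaline",
                     ATROPINE = "atropine", AMIODARONE = "amiodarone")
drug_marker_dose <- c(adrenaline = "1 mg", atropine = "3 mg",
                      amiodarone = "300 mg")

assert_rhythm <- function(rhythm) {
  if (!(is.character(rhythm) && length(rhythm) == 1 &&
        rhythm %in% rhythm_levels)) {
    stop("rhythm must be one of ", paste(rhythm_levels, collapse = ", "),
         call. = FALSE)
  }
  rhythm
}

#' Create the baseline arrested patient
#'
#' All three scenario patients share one baseline: cardiac output has decayed
#' to zero, neuromuscular blockade is fixed at 100%, inspired oxygen fraction
#' at 0.80, ischemic index averaging at 0.99, ischemic index sensitivity at
#' 0.5 and both ventricular contractility factors at 0.5.  They differ only
#' in the initial rhythm (the rhythm-override choice): asystole, coarse
#' ventricular fibrillation or pulseless ventricular tachycardia.  Sinus
#' rhythm is rejected — the scenario starts in cardiac arrest.
#'
#' The returned state also carries the bookkeeping the engine maintains: the
#' `drug_conditioning_armed` flag (set by the second-adrenaline or amiodarone
#' marker) and `no_cc_elapsed`, the seconds since compressions last stopped.
#'
#' @param initial_rhythm one of `"ASY"`, `"cVF"`, `"pVT"`.
#' @return An object of class `patient_state` (a named list with fields
#'   `rhythm`, `sbp`, `cardiac_output`, `iis`, `iia`, `cf_lv`, `cf_rv`,
#'   `fio2`, `nmb`, `drug_conditioning_armed`, `no_cc_elapsed`).
#' @examples
#' p <- initialize_patient("cVF")
#' p$cardiac_output  # 0 at baseline
#' @export
initialize_patient <- function(initial_rhythm) {
  assert_rhythm(initial_rhythm)
  if (initial_rhythm == "SR") {
    stop("initial rhythm must be an arrest rhythm (ASY, cVF or pVT), not SR",
         call. = FALSE)
  }
  structure(list(
    rhythm = initial_rhythm,
    sbp = 0,
    cardiac_output = 0,
    iis = 0.5,
    iia = 0.99,
    cf_lv = 0.5,
    cf_rv = 0.5,
    fio2 = 0.80,
    nmb = 100,
    drug_conditioning_armed = FALSE,
    no_cc_elapsed = 0
  ), class = "patient_state")
}

#' Classify a delivered defibrillation
#'
#' Shocks at or below the recording floor (default 10 J, strict "more than")
#' are `"ignored"` — the scenario does not record them.  Recorded shocks are
#' `"indicated"` when the rhythm at delivery is shockable (cVF or pVT) and
#' `"non_indicated"` during asystole or sinus rhythm.
#'
#' @param rhythm rhythm at the instant of shock delivery.
#' @param energy delivered energy in joules (>= 0).
#' @param floor recording floor in joules.
#' @return `"indicated"`, `"non_indicated"` or `"ignored"`.
#' @examples
#' classify_defibrillation("cVF", 150) # indicated
#' classify_defibrillation("cVF", 10)  # ignored (strictly more than 10 J)
#' @export
classify_defibrillation <- function(rhythm, energy, floor = 10) {
  assert_rhythm(rhythm)
  stopifnot(is.numeric(energy), length(energy) == 1, energy >= 0)
  if (energy <= floor) return("ignored")
  if (rhythm %in% shockable_rhythms) "indicated" else "non_indicated"
}

#' Apply an observer marker click to the patient
#'
#' The six marker states are time marks; only three alter physiology.  The
#' second-adrenaline and amiodarone markers set the ischemic index
#' sensitivity to 0.5 and arm the drug-conditioning chain (drugs must then be
#' circulated by compressions before a shock can convert).  The atropine
#' marker sets the right-ventricular contractility factor to 0.8.  IV-line,
#' intubation and first-adrenaline markers leave the physiology untouched.
#' Repeated clicks are idempotent.
#'
#' @param state a `patient_state`.
#' @param marker_name one of [marker_levels].
#' @return The updated `patient_state`.
#' @export
apply_marker <- function(state, marker_name) {
  stopifnot(inherits(state, "patient_state"))
  if (!(is.character(marker_name) && length(marker_name) == 1 &&
        marker_name %in% marker_levels)) {
    stop("marker_name must be one of ", paste(marker_levels, collapse = ", "),
         call. = FALSE)
  }
  if (marker_name %in% c("EPI_2", "AMIODARONE")) {
    state$iis <- 0.5
    state$drug_conditioning_armed <- TRUE
  } else if (marker_name == "ATROPINE") {
    state$cf_rv <- 0.8
  }
  state
}

#' Circulate administered drugs with chest compressions
#'
#' Models drug transport to the target receptors: once the conditioning chain
#' is armed (second adrenaline or amiodarone) and the ischemic index
#' sensitivity is 0.5, performing chest compressions raises the
#' left-ventricular contractility factor to 0.8 — the condition under which a
#' defibrillation can convert a shockable rhythm to sinus.  Without active
#' compressions, or before arming, the state is unchanged.
#'
#' @param state a `patient_state`.
#' @param compressions_active logical; are chest compressions being
#'   performed.
#' @return The updated `patient_state`.
#' @export
condition_on_compressions <- function(state, compressions_active) {
  stopifnot(inherits(state, "patient_state"),
            is.logical(compressions_active), length(compressions_active) == 1)
  if (isTRUE(compressions_active) && state$drug_conditioning_armed &&
      state$iis == 0.5) {
    state$cf_lv <- 0.8
  }
  state
}

#' Outcome of a delivered shock
#'
#' A recorded shock converts the rhythm to sinus (the ROSC event) only when
#' the rhythm is shockable (cVF or pVT) and the left-ventricular
#' contractility factor has been raised to 0.8 by the drug-then-compressions
#' chain.  Every other combination — ignored energy, asystole, sinus, or an
#' unconditioned ventricle — leaves the rhythm unchanged.
#'
#' @param state a `patient_state`.
#' @param energy delivered energy in joules.
#' @param cfg a [guideline_config()].
#' @return The updated `patient_state`.
#' @export
defibrillation_outcome <- function(state, energy, cfg = guideline_config()) {
  stopifnot(inherits(state, "patient_state"))
  cls <- classify_defibrillation(state$rhythm, energy, cfg$shock_energy_floor)
  if (cls == "indicated" && state$cf_lv == 0.8) {
    state$rhythm <- "SR"
  }
  state
}

#' Degeneration of an unsupported shockable rhythm
#'
#' When the rhythm is ventricular fibrillation or pulseless ventricular
#' tachycardia and no chest compressions have been performed for strictly
#' more than the timeout (default 60 s), the rhythm degenerates to asystole.
#' The elapsed no-compression time is read from `state$no_cc_elapsed`.
#'
#' @param state a `patient_state`.
#' @param cfg a [guideline_config()].
#' @return The updated `patient_state`.
#' @export
degrade_to_asystole <- function(state, cfg = guideline_config()) {
  stopifnot(inherits(state, "patient_state"))
  if (state$rhythm %in% shockable_rhythms &&
      state$no_cc_elapsed > cfg$asystole_degeneration_timeout) {
    state$rhythm <- "ASY"
  }
  state
}

#' Surrogate hemodynamic kernel
#'
#' A three-regime piecewise stand-in for a full physiologic model, sufficient
#' for the performance metrics: during arrest without compressions there is
#' no flow (SBP 0, cardiac output 0); during compressions the patient is
#' perfused at the team's compression output with an SBP above the 40 mmHg
#' chest-compression gate; after ROSC (sinus rhythm) the patient sits on a
#' fixed plateau (SBP 120 mmHg, cardiac output 5 L/min by default).
#'
#' @param state a `patient_state`.
#' @param compressions_active logical.
#' @param profile_cc_output cardiac output generated by this team's
#'   compressions, L/min (> 0).
#' @param cfg a [guideline_config()].
#' @return The updated `patient_state` with `sbp` and `cardiac_output` set.
#' @export
surrogate_hemodynamics <- function(state, compressions_active,
                                   profile_cc_output,
                                   cfg = guideline_config()) {
  stopifnot(inherits(state, "patient_state"),
            is.numeric(profile_cc_output), profile_cc_output > 0)
  if (state$rhythm == "SR") {
    state$sbp <- cfg$rosc_sbp
    state$cardiac_output <- cfg$rosc_cardiac_output
  } else if (isTRUE(compressions_active)) {
    state$sbp <- cfg$cc_sbp
    state$cardiac_output <- profile_cc_output
  } else {
    state$sbp <- 0
    state$cardiac_output <- 0
  }
  state
}

# Full surrogate channel set for one physio sample (vectorised over regimes
# is unnecessary; callers loop over few samples).
kernel_channels <- function(rhythm, compressions_active, profile_cc_output,
                            cfg) {
  if (rhythm == "SR") {
    c(hr = cfg$rosc_hr, sbp = cfg$rosc_sbp, dbp = cfg$rosc_dbp,
      cardiac_output = cfg$rosc_cardiac_output, spo2 = cfg$rosc_spo2)
  } else if (compressions_active) {
    c(hr = cfg$cc_hr, sbp = cfg$cc_sbp, dbp = cfg$cc_dbp,
      cardiac_output = profile_cc_output, spo2 = cfg$cc_spo2)
  } else {
    c(hr = 0, sbp = 0, dbp = 0, cardiac_output = 0, spo2 = cfg$noflow_spo2)
  }
}

#' @export
print.patient_state <- function(x, ...) {
  cat("<patient_state>\n")
  cat("  rhythm:", x$rhythm,
      " SBP:", x$sbp, "mmHg  CO:", x$cardiac_output, "L/min\n")
  cat("  IIS:", x$iis, " CF-LV:", x$cf_lv, " CF-RV:", x$cf_rv,
      " armed:", x$drug_conditioning_armed, "\n")
  invisible(x)
}
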