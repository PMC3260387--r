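#' Build a trainee action stream
#'
#' An action stream is a data frame of timestamped trainee actions, the
#' engine's sole input besides the initial rhythm.  Kinds are `cc_start` /
#' `cc_stop` (chest-compression segment boundaries), `ventilation` (an
#' instantaneous counted breath), `defibrillation` (requires `energy` in
#' joules) and `marker` (requires `marker`, one of [marker_levels]).
#'
#' @param time seconds from scenario start (>= 0, non-decreasing).
#' @param kind one of `"cc_start"`, `"cc_stop"`, `"ventilation"`,
#'   `"defibrillation"`, `"marker"` (recycled against `time`).
#' @param energy joules, `NA` except for defibrillations.
#' @param marker marker name, `NA` except for marker events.
#' @return A validated `data.frame` with class `action_stream`.
#' @examples
#' action_stream(c(10, 95), c("cc_start", "defibrillation"),
#'               energy = c(NA, 150))
#' @export
action_stream <- function(time = numeric(), kind = character(),
                          energy = NA_real_, marker = NA_character_) {
  n <- length(time)
  df <- data.frame(
    time = as.numeric(time),
    kind = rep_len(as.character(kind), n),
    energy = rep_len(as.numeric(energy), n),
    marker = rep_len(as.character(marker), n),
    stringsAsFactors = FALSE
  )
  validate_action_stream(df)
}

action_kinds <- c("cc_start", "cc_stop", "ventilation", "defibrillation",
                  "marker")

#' @rdname action_stream
#' @param actions a data frame to validate.
#' @export
validate_action_stream <- function(actions) {
  stopifnot(is.data.frame(actions))
  req <- c("time", "kind")
  if (!all(req %in% names(actions))) {
    stop("action stream needs columns 'time' and 'kind'", call. = FALSE)
  }
  if (is.null(actions$energy)) actions$energy <- NA_real_
  if (is.null(actions$marker)) actions$marker <- NA_character_
  actions$time <- as.numeric(actions$time)
  actions$energy <- as.numeric(actions$energy)
  actions$marker <- as.character(actions$marker)
  if (nrow(actions) > 0) {
    if (anyNA(actions$time) || any(actions$time < 0)) {
      stop("action times must be non-negative numbers", call. = FALSE)
    }
    if (is.unsorted(actions$time)) {
      stop("action stream must be sorted by time", call. = FALSE)
    }
    bad <- !(actions$kind %in% action_kinds)
    if (any(bad)) {
      stop("unknown action kind(s): ",
           paste(unique(actions$kind[bad]), collapse = ", "), call. = FALSE)
    }
    is_defib <- actions$kind == "defibrillation"
    if (any(is_defib & (is.na(actions$energy) | actions$energy < 0))) {
      stop("defibrillation events need a non-negative energy", call. = FALSE)
    }
    if (any(!is_defib & !is.na(actions$energy))) {
      stop("energy is only valid on defibrillation events", call. = FALSE)
    }
    is_marker <- actions$kind == "marker"
    if (any(is_marker & !(actions$marker %in% marker_levels))) {
      stop("marker events need a marker name from marker_levels",
           call. = FALSE)
    }
  }
  class(actions) <- c("action_stream", "data.frame")
  actions
}

#' Scenario state container
#'
#' @param value one of [scenario_state_levels].
#' @param entered_at seconds at which the state was entered.
#' @return A list with class `scenario_state`.
#' @export
scenario_state <- function(value = "NO_CC", entered_at = 0) {
  stopifnot(value %in% scenario_state_levels, entered_at >= 0)
  structure(list(value = value, entered_at = as.numeric(entered_at)),
            class = "scenario_state")
}

#' One step of the scenario state machine
#'
#' Computes the sequence of scenario states traversed when one trainee
#' action arrives.  Compressions that perfuse the patient above the 40 mmHg
#' systolic gate enter `CC`; compressions that do not enter
#' `INEFFECTIVE_RESUSCITATION`.  A ventilation passes through `VENTILATION`
#' and returns to the prior compression state.  A recorded shock passes
#' through `DEFIB` and then `DEFIB_INDICATED` or `DEFIB_NON_INDICATED`
#' according to [classify_defibrillation()].  A marker passes through its
#' `MARKER_*` state and always returns to `NO_CC` first (resuming `CC` if
#' compressions are ongoing).  `EXIT` is reached only by the operator ending
#' the scenario, never by this function.
#'
#' @param scenario a [scenario_state()].
#' @param patient the `patient_state` after the event's physiologic effect.
#' @param event a one-row [action_stream()].
#' @param cfg a [guideline_config()].
#' @return Character vector of states traversed, in order; empty for an
#'   ignored (at-or-below-floor) shock.  The last element is the resulting
#'   state.
#' @export
scenario_transition <- function(scenario, patient, event,
                                cfg = guideline_config()) {
  stopifnot(inherits(scenario, "scenario_state"),
            inherits(patient, "patient_state"),
            is.data.frame(event), nrow(event) == 1)
  if (event$time < scenario$entered_at) {
    stop("out-of-order event: time ", event$time,
         " precedes state entry at ", scenario$entered_at, call. = FALSE)
  }
  in_cc <- scenario$value == "CC"
  switch(event$kind,
    cc_start = {
      if (patient$sbp > cfg$cc_sbp_threshold) "CC"
      else "INEFFECTIVE_RESUSCITATION"
    },
    cc_stop = "NO_CC",
    ventilation = c("VENTILATION", if (in_cc) "CC" else "NO_CC"),
    defibrillation = {
      cls <- classify_defibrillation(patient$rhythm, event$energy,
                                     cfg$shock_energy_floor)
      if (cls == "ignored") character(0)
      else c("DEFIB",
             if (cls == "indicated") "DEFIB_INDICATED"
             else "DEFIB_NON_INDICATED",
             if (in_cc) "CC" else "NO_CC")
    },
    marker = c(paste0("MARKER_", event$marker), "NO_CC",
               if (in_cc) "CC"),
    stop("unknown action kind: ", event$kind, call. = FALSE)
  )
}

#' Replay a trainee action stream through the scenario machine
#'
#' The engine is a deterministic function of its inputs.  It maintains the
#' patient and scenario state, applies the drug-to-compressions-to-shock
#' effectiveness chain, degenerates an unsupported shockable rhythm to
#' asystole after the timeout, and emits the three log streams: every state
#' entry, rhythm change, recorded shock (with energy and classification),
#' compression boundary, ventilation and marker goes to the event log; the
#' surrogate hemodynamics are sampled into the physio log at a fixed
#' interval; drug markers additionally produce drug-log records.  The
#' scenario ends with an operator `EXIT` at `horizon`; actions after the
#' horizon are discarded.
#'
#' Timing conventions: times are in whole seconds; simultaneous actions are
#' processed in stream order; an action timed exactly at the degeneration
#' deadline is processed first (the timeout is a strict inequality); a
#' physio sample at time *t* reflects the state immediately before any
#' event at *t*, so the sample taken at the ROSC instant is still a
#' pre-ROSC sample.
#'
#' @param actions an [action_stream()] (possibly empty).
#' @param initial_rhythm `"ASY"`, `"cVF"` or `"pVT"`.
#' @param cfg a [guideline_config()].
#' @param profile_cc_output cardiac output generated by compressions, L/min.
#' @param physio_sample_interval seconds between physio samples (> 0).
#' @param horizon scenario length in seconds (> 0).
#' @return A list with components `event` ([event_log()]), `physio`
#'   ([physio_log()]) and `drug` ([drug_log()]).
#' @examples
#' acts <- action_stream(c(5, 95), c("cc_start", "defibrillation"),
#'                       energy = c(NA, 150))
#' logs <- run_engine(acts, "cVF", horizon = 120)
#' subset(logs$event, code == "DEFIB")
#' @export
run_engine <- function(actions, initial_rhythm, cfg = guideline_config(),
                       profile_cc_output = 1.5, physio_sample_interval = 5,
                       horizon = 600) {
  actions <- validate_action_stream(actions)
  stopifnot(is.numeric(physio_sample_interval), physio_sample_interval > 0,
            is.numeric(horizon), horizon > 0)
  actions <- actions[actions$time <= horizon, , drop = FALSE]

  patient <- initialize_patient(initial_rhythm)
  cc_active <- FALSE
  cc_off_since <- 0        # compressions have never run: timer starts at 0
  scen <- scenario_state("NO_CC", 0)

  # record accumulators; pre-sized lists grown by counter
  ev_t <- numeric(256); ev_c <- character(256); ev_d <- character(256)
  n_ev <- 0L
  add_ev <- function(t, code, detail = "") {
    n_ev <<- n_ev + 1L
    if (n_ev > length(ev_t)) {
      ev_t <<- c(ev_t, numeric(length(ev_t)))
      ev_c <<- c(ev_c, character(length(ev_c)))
      ev_d <<- c(ev_d, character(length(ev_d)))
    }
    ev_t[n_ev] <<- t; ev_c[n_ev] <<- code; ev_d[n_ev] <<- detail
  }
  drg_t <- numeric(); drg_n <- character(); drg_d <- character()
  # state-change timeline for physio sampling
  ch_t <- 0; ch_cc <- FALSE; ch_rh <- patient$rhythm

  note_change <- function(t) {
    ch_t <<- c(ch_t, t); ch_cc <<- c(ch_cc, cc_active)
    ch_rh <<- c(ch_rh, patient$rhythm)
  }
  enter_states <- function(t, path) {
    for (s in path) add_ev(t, "STATE", s)
    if (length(path) > 0) scen <<- scenario_state(path[[length(path)]], t)
  }

  add_ev(0, "STATE", "NO_CC")
  add_ev(0, "RHYTHM", patient$rhythm)

  i <- 1L
  n <- nrow(actions)
  repeat {
    deg_time <- if (!cc_active && patient$rhythm %in% shockable_rhythms) {
      cc_off_since + cfg$asystole_degeneration_timeout
    } else Inf
    a_time <- if (i <= n) actions$time[[i]] else Inf
    if (a_time <= deg_time && a_time <= horizon) {
      event <- actions[i, , drop = FALSE]
      i <- i + 1L
      t <- event$time
      patient$no_cc_elapsed <- if (cc_active) 0 else t - cc_off_since
      kind <- event$kind
      if (kind == "cc_start") {
        if (!cc_active) {
          cc_active <- TRUE
          patient <- condition_on_compressions(patient, TRUE)
          patient <- surrogate_hemodynamics(patient, TRUE, profile_cc_output,
                                            cfg)
          add_ev(t, "CC_ON")
          enter_states(t, scenario_transition(scen, patient, event, cfg))
          note_change(t)
        }
      } else if (kind == "cc_stop") {
        if (cc_active) {
          cc_active <- FALSE
          cc_off_since <- t
          patient <- surrogate_hemodynamics(patient, FALSE, profile_cc_output,
                                            cfg)
          add_ev(t, "CC_OFF")
          enter_states(t, scenario_transition(scen, patient, event, cfg))
          note_change(t)
        }
      } else if (kind == "ventilation") {
        add_ev(t, "VENT")
        enter_states(t, scenario_transition(scen, patient, event, cfg))
      } else if (kind == "defibrillation") {
        cls <- classify_defibrillation(patient$rhythm, event$energy,
                                       cfg$shock_energy_floor)
        if (cls != "ignored") {
          if (event$energy > cfg$shock_energy_cap) {
            add_ev(t, "WARN", sprintf(
              "energy %sJ exceeds advisory cap %sJ",
              format(event$energy, trim = TRUE),
              format(cfg$shock_energy_cap, trim = TRUE)))
          }
          path <- scenario_transition(scen, patient, event, cfg)
          # record the shock between the DEFIB state and its classification
          add_ev(t, "STATE", path[[1]])
          add_ev(t, "DEFIB", sprintf("%sJ %s",
                                     format(event$energy, trim = TRUE), cls))
          enter_states(t, path[-1])
          scen <- scenario_state(path[[length(path)]], t)
          before <- patient$rhythm
          patient <- defibrillation_outcome(patient, event$energy, cfg)
          if (patient$rhythm != before) {
            patient <- surrogate_hemodynamics(patient, cc_active,
                                              profile_cc_output, cfg)
            add_ev(t, "RHYTHM", patient$rhythm)
            add_ev(t, "ROSC")
            note_change(t)
          }
        }
      } else if (kind == "marker") {
        patient <- apply_marker(patient, event$marker)
        add_ev(t, "MARKER", event$marker)
        enter_states(t, scenario_transition(scen, patient, event, cfg))
        if (cc_active) {
          patient <- condition_on_compressions(patient, TRUE)
        }
        if (event$marker %in% names(drug_marker_map)) {
          drug <- drug_marker_map[[event$marker]]
          drg_t <- c(drg_t, t)
          drg_n <- c(drg_n, drug)
          drg_d <- c(drg_d, drug_marker_dose[[drug]])
        }
      }
    } else if (deg_time < a_time && deg_time <= horizon) {
      # timeout elapses: shockable rhythm degenerates to asystole.  The flip
      # is logged at the deadline instant (conceptually just past it, the
      # strict inequality having been crossed).
      patient$no_cc_elapsed <- deg_time - cc_off_since
      patient$rhythm <- "ASY"
      add_ev(deg_time, "RHYTHM", "ASY")
      note_change(deg_time)
    } else {
      break
    }
  }
  add_ev(horizon, "STATE", "EXIT")

  event <- event_log(time = ev_t[seq_len(n_ev)], code = ev_c[seq_len(n_ev)],
                     detail = ev_d[seq_len(n_ev)])

  sample_times <- seq(0, horizon, by = physio_sample_interval)
  # state at t-minus: last change strictly before the sample time
  idx <- pmax(1L, findInterval(sample_times - 0.5, ch_t))
  ch <- t(vapply(seq_along(sample_times), function(k) {
    kernel_channels(ch_rh[[idx[[k]]]], ch_cc[[idx[[k]]]], profile_cc_output,
                    cfg)
  }, numeric(5)))
  physio <- physio_log(time = sample_times, hr = ch[, "hr"],
                       sbp = ch[, "sbp"], dbp = ch[, "dbp"],
                       cardiac_output = ch[, "cardiac_output"],
                       spo2 = ch[, "spo2"])
  drug <- drug_log(time = drg_t, drug = drg_n, dose = drg_d)
  list(event = event, physio = physio, drug = drug)
}
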