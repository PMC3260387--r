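#' Scenario guideline and kernel configuration
#'
#' Bundles the guideline-derived thresholds of the scenario script together
#' with the constants of the surrogate hemodynamic kernel.  All engine and
#' metrics operations take a `guideline_config` so every threshold is
#' overridable in one place.
#'
#' The defaults encode the scripted scenario's rules: shocks are recorded
#' only above 10 J; energies above 200 J are processed but flagged (the cap
#' is a safety advisory for trainees, not an engine rule); the guideline
#' rhythm-check cycle is 120 s; a shockable rhythm left without compressions
#' for more than 60 s degenerates to asystole; the chest-compression state is
#' entered when systolic pressure exceeds 40 mmHg.
#'
#' @param shock_energy_floor joules; shocks at or below this energy are not
#'   recorded (strictly "more than" the floor counts).
#' @param shock_energy_cap joules; advisory maximum, exceeding it adds a
#'   `WARN` record to the event log.
#' @param target_shock_interval seconds; guideline defibrillation cycle
#'   against which the mean absolute interval deviation is computed.
#' @param asystole_degeneration_timeout seconds without compressions after
#'   which a shockable rhythm degenerates to asystole (strict inequality).
#' @param cc_sbp_threshold mmHg; systolic pressure above which the scenario
#'   enters the chest-compression state.
#' @param cc_sbp,cc_dbp,cc_hr,cc_spo2 surrogate kernel values during
#'   compressions before ROSC (mmHg, mmHg, min^-1, percent).
#' @param noflow_spo2 surrogate oxygen saturation during arrest without
#'   compressions (percent); other no-flow channels are zero.
#' @param rosc_sbp,rosc_dbp,rosc_hr,rosc_spo2,rosc_cardiac_output surrogate
#'   kernel plateau after return of spontaneous circulation.
#' @return An object of class `guideline_config` (a named list).
#' @examples
#' cfg <- guideline_config()
#' cfg$target_shock_interval
#' @export
guideline_config <- function(shock_energy_floor = 10,
                             shock_energy_cap = 200,
                             target_shock_interval = 120,
                             asystole_degeneration_timeout = 60,
                             cc_sbp_threshold = 40,
                             cc_sbp = 60,
                             cc_dbp = 20,
                             cc_hr = 0,
                             cc_spo2 = 70,
                             noflow_spo2 = 55,
                             rosc_sbp = 120,
                             rosc_dbp = 80,
                             rosc_hr = 80,
                             rosc_spo2 = 97,
                             rosc_cardiac_output = 5.0) {
  cfg <- list(
    shock_energy_floor = as.numeric(shock_energy_floor),
    shock_energy_cap = as.numeric(shock_energy_cap),
    target_shock_interval = as.numeric(target_shock_interval),
    asystole_degeneration_timeout = as.numeric(asystole_degeneration_timeout),
    cc_sbp_threshold = as.numeric(cc_sbp_threshold),
    cc_sbp = as.numeric(cc_sbp),
    cc_dbp = as.numeric(cc_dbp),
    cc_hr = as.numeric(cc_hr),
    cc_spo2 = as.numeric(cc_spo2),
    noflow_spo2 = as.numeric(noflow_spo2),
    rosc_sbp = as.numeric(rosc_sbp),
    rosc_dbp = as.numeric(rosc_dbp),
    rosc_hr = as.numeric(rosc_hr),
    rosc_spo2 = as.numeric(rosc_spo2),
    rosc_cardiac_output = as.numeric(rosc_cardiac_output)
  )
  thresholds <- c("shock_energy_floor", "shock_energy_cap",
                  "target_shock_interval", "asystole_degeneration_timeout",
                  "cc_sbp_threshold")
  for (nm in thresholds) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("guideline_config: '", nm, "' must be strictly positive",
           call. = FALSE)
    }
  }
  if (cfg$shock_energy_floor >= cfg$shock_energy_cap) {
    stop("guideline_config: shock_energy_floor must be below shock_energy_cap",
         call. = FALSE)
  }
  structure(cfg, class = "guideline_config")
}

#' Read or write a guideline configuration as a flat key-value file
#'
#' The on-disk form is a two-column tab-separated file (`key<TAB>value`), one
#' constant per line.  Unknown keys are rejected; omitted keys keep their
#' defaults.
#'
#' @param path file path.
#' @param cfg a [guideline_config()] object.
#' @return `read_guideline_config` returns a `guideline_config`;
#'   `write_guideline_config` returns `path` invisibly.
#' @export
read_guideline_config <- function(path) {
  kv <- read_kv_file(path)
  known <- names(formals(guideline_config))
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0) {
    stop("unknown guideline_config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(guideline_config, lapply(kv, as.numeric))
}

#' @rdname read_guideline_config
#' @export
write_guideline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "guideline_config"))
  write_kv_file(unclass(cfg), path)
}

# Shared flat key-value (TAB-separated) file helpers. NA serialises as "NA".
read_kv_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("malformed key-value line ", i, " in ", path, ": '", lines[[i]],
           "'", call. = FALSE)
    }
    out[[parts[[1]]]] <- parts[[2]]
  }
  out
}

write_kv_file <- function(x, path) {
  vals <- vapply(x, function(v) {
    if (length(v) != 1) stop("key-value entries must be scalars", call. = FALSE)
    if (is.na(v)) "NA"
    else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  writeLines(paste(names(x), vals, sep = "\t"), path)
  invisible(path)
}
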