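#' The three scenario log streams
#'
#' A scenario produces three tab-separated, UTF-8, plain-text streams, each
#' with a mandatory one-line header and integer-second elapsed times:
#'
#' * **event log** (`event.tsv`, columns `time`, `code`, `detail`): every
#'   scenario-state entry (`STATE`), rhythm change (`RHYTHM`), recorded
#'   shock (`DEFIB`, detail `"<energy>J <classification>"`), marker click
#'   (`MARKER`), ventilation (`VENT`), compression boundary
#'   (`CC_ON`/`CC_OFF`), return of spontaneous circulation (`ROSC`) and
#'   warning (`WARN`).
#' * **physio log** (`physio.tsv`, columns `time`, `hr`, `sbp`, `dbp`,
#'   `cardiac_output`, `spo2`): the surrogate hemodynamics sampled at a
#'   fixed interval.
#' * **drug log** (`drug.tsv`, columns `time`, `drug`, `dose`): one record
#'   per drug marker (adrenaline, atropine, amiodarone) with a dose string.
#'
#' Times must be non-decreasing within a stream.  Reading a written log
#' reproduces it exactly (round-trip contract).
#'
#' @param time seconds from scenario start.
#' @param code event code (see above).
#' @param detail free-text payload (no tabs); energy and classification for
#'   `DEFIB`, state name for `STATE`, rhythm for `RHYTHM`, marker name for
#'   `MARKER`.
#' @param hr,sbp,dbp,cardiac_output,spo2 physio channels (min^-1, mmHg,
#'   mmHg, L/min, percent).
#' @param drug one of `"adrenaline"`, `"atropine"`, `"amiodarone"`.
#' @param dose dose string, e.g. `"1 mg"`.
#' @return A classed `data.frame` (`event_log`, `physio_log` or `drug_log`).
#' @name scenario-logs
NULL

event_codes <- c("STATE", "RHYTHM", "DEFIB", "MARKER", "VENT",
                 "CC_ON", "CC_OFF", "ROSC", "WARN")
drug_levels <- c("adrenaline", "atropine", "amiodarone")

#' @rdname scenario-logs
#' @export
event_log <- function(time = numeric(), code = character(),
                      detail = character()) {
  n <- length(time)
  if (length(detail) == 0 && n > 0) detail <- rep("", n)
  df <- data.frame(time = as.numeric(time), code = as.character(code),
                   detail = as.character(detail), stringsAsFactors = FALSE)
  validate_log(df, "event_log")
}

#' @rdname scenario-logs
#' @export
physio_log <- function(time = numeric(), hr = numeric(), sbp = numeric(),
                       dbp = numeric(), cardiac_output = numeric(),
                       spo2 = numeric()) {
  df <- data.frame(time = as.numeric(time), hr = as.numeric(hr),
                   sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                   cardiac_output = as.numeric(cardiac_output),
                   spo2 = as.numeric(spo2), stringsAsFactors = FALSE)
  validate_log(df, "physio_log")
}

#' @rdname scenario-logs
#' @export
drug_log <- function(time = numeric(), drug = character(),
                     dose = character()) {
  df <- data.frame(time = as.numeric(time), drug = as.character(drug),
                   dose = as.character(dose), stringsAsFactors = FALSE)
  validate_log(df, "drug_log")
}

log_columns <- list(
  event_log = c("time", "code", "detail"),
  physio_log = c("time", "hr", "sbp", "dbp", "cardiac_output", "spo2"),
  drug_log = c("time", "drug", "dose")
)

validate_log <- function(df, what) {
  cols <- log_columns[[what]]
  stopifnot(is.data.frame(df), identical(names(df), cols))
  if (nrow(df) > 0) {
    if (anyNA(df$time) || any(df$time < 0)) {
      stop(what, ": times must be non-negative", call. = FALSE)
    }
    if (is.unsorted(df$time)) {
      stop(what, ": times must be non-decreasing", call. = FALSE)
    }
    if (what == "event_log") {
      bad <- !(df$code %in% event_codes)
      if (any(bad)) {
        stop("event_log: unknown code(s): ",
             paste(unique(df$code[bad]), collapse = ", "), call. = FALSE)
      }
      for (k in which(df$code == "DEFIB")) {
        parse_defib_detail(df$detail[[k]])
      }
    }
    if (what == "drug_log" && any(!(df$drug %in% drug_levels))) {
      stop("drug_log: drug must be one of ",
           paste(drug_levels, collapse = ", "), call. = FALSE)
    }
    if (what == "physio_log") {
      num <- as.matrix(df[, -1])
      if (anyNA(num) || any(num < 0)) {
        stop("physio_log: all channels must be non-negative numbers",
             call. = FALSE)
      }
    }
  }
  class(df) <- c(what, "data.frame")
  df
}

parse_defib_detail <- function(detail) {
  m <- regmatches(detail,
                  regexec("^([0-9]+(?:\\.[0-9]+)?)J (indicated|non_indicated)$",
                          detail))[[1]]
  if (length(m) != 3) {
    stop("unparseable DEFIB detail: '", detail, "'", call. = FALSE)
  }
  list(energy = as.numeric(m[[2]]), classification = m[[3]])
}

format_log_value <- function(x) {
  if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  else as.character(x)
}

write_log_file <- function(df, path) {
  cols <- names(df)
  body <- do.call(paste, c(lapply(df, format_log_value), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), if (nrow(df) > 0) body),
             con, useBytes = TRUE)
  invisible(path)
}

read_log_file <- function(path, what) {
  cols <- log_columns[[what]]
  if (!file.exists(path)) {
    stop("log file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    stop(path, ": missing header line", call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols)) {
    stop(path, ": bad header, expected '", paste(cols, collapse = "\t"),
         "'", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  numeric_cols <- if (what == "physio_log") cols else "time"
  out <- lapply(cols, function(cl) {
    if (cl %in% numeric_cols) numeric(length(body)) else character(length(body))
  })
  names(out) <- cols
  prev_time <- -Inf
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    lineno <- k + 1L
    # the detail column may legitimately be empty (trailing field)
    if (length(f) == length(cols) - 1 && what == "event_log") f <- c(f, "")
    if (length(f) != length(cols)) {
      stop(path, " line ", lineno, ": expected ", length(cols),
           " tab-separated fields, found ", length(f), call. = FALSE)
    }
    for (j in seq_along(cols)) {
      cl <- cols[[j]]
      if (cl %in% numeric_cols) {
        v <- suppressWarnings(as.numeric(f[[j]]))
        if (is.na(v)) {
          stop(path, " line ", lineno, ": unparseable number '", f[[j]],
               "' in column '", cl, "'", call. = FALSE)
        }
        out[[cl]][[k]] <- v
      } else {
        out[[cl]][[k]] <- f[[j]]
      }
    }
    if (out$time[[k]] < prev_time) {
      stop(path, " line ", lineno, ": time goes backwards (",
           format_log_value(out$time[[k]]), " after ",
           format_log_value(prev_time), ")", call. = FALSE)
    }
    prev_time <- out$time[[k]]
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  tryCatch(validate_log(df, what), error = function(e) {
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Write the three scenario logs to a directory
#'
#' Writes `event.tsv`, `physio.tsv` and `drug.tsv` in the dialect described
#' under [scenario-logs].  Reading the files back reproduces the in-memory
#' logs exactly.
#'
#' @param event,physio,drug the three log objects.
#' @param directory destination directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_scenario_logs <- function(event, physio, drug, directory) {
  event <- validate_log(as.data.frame(event), "event_log")
  physio <- validate_log(as.data.frame(physio), "physio_log")
  drug <- validate_log(as.data.frame(drug), "drug_log")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  write_log_file(event, file.path(directory, "event.tsv"))
  write_log_file(physio, file.path(directory, "physio.tsv"))
  write_log_file(drug, file.path(directory, "drug.tsv"))
  invisible(directory)
}

#' Read scenario logs
#'
#' Readers for the individual streams and a convenience wrapper for a
#' directory holding all three (`event.tsv`, `physio.tsv`, `drug.tsv`).
#' Malformed input is rejected with the offending line number.
#'
#' @param path path to a single log file.
#' @param directory directory holding the three files.
#' @return The corresponding log object; `read_scenario_logs` returns a list
#'   with components `event`, `physio`, `drug`.
#' @export
read_event_log <- function(path) read_log_file(path, "event_log")

#' @rdname read_event_log
#' @export
read_physio_log <- function(path) read_log_file(path, "physio_log")

#' @rdname read_event_log
#' @export
read_drug_log <- function(path) read_log_file(path, "drug_log")

#' @rdname read_event_log
#' @export
read_scenario_logs <- function(directory) {
  list(event = read_event_log(file.path(directory, "event.tsv")),
       physio = read_physio_log(file.path(directory, "physio.tsv")),
       drug = read_drug_log(file.path(directory, "drug.tsv")))
}

#' Convert between seconds and "MM:SS" clock strings
#'
#' `parse_mmss` accepts `"M:SS"` or `"MM:SS"` (minutes may exceed two digits
#' for long scenarios; seconds must be two digits below 60).  `format_mmss`
#' rounds to the nearest whole second and zero-pads both fields.  The two
#' are exact inverses on non-negative whole seconds; `format_mmss(parse_mmss(x))`
#' canonicalises (`"7:43"` becomes `"07:43"`).
#'
#' @param text a clock string.
#' @param seconds a non-negative number of seconds.
#' @return `parse_mmss`: seconds as a number; `format_mmss`: a string.
#' @examples
#' parse_mmss("18:09")  # 1089
#' format_mmss(728)     # "12:08"
#' @export
parse_mmss <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec("^([0-9]+):([0-9]{2})$", text))[[1]]
  if (length(m) != 3) {
    stop("not an MM:SS clock string: '", text, "'", call. = FALSE)
  }
  secs <- as.numeric(m[[3]])
  if (secs >= 60) {
    stop("seconds field must be below 60 in '", text, "'", call. = FALSE)
  }
  as.numeric(m[[2]]) * 60 + secs
}

#' @rdname parse_mmss
#' @export
format_mmss <- function(seconds) {
  stopifnot(is.numeric(seconds), length(seconds) == 1)
  if (is.na(seconds)) return(NA_character_)
  if (seconds < 0) stop("cannot format negative seconds", call. = FALSE)
  s <- round(seconds)
  sprintf("%02d:%02d", s %/% 60, s %% 60)
}
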