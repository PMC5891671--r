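#' Keystroke logs: data model and file dialect
#'
#' A subject log is the raw unit of analysis: the ordered sequence of key
#' press/release timestamps captured for one subject in one typing setting
#' (a controlled in-clinic transcription task, `"CLINIC"`, or naturalistic
#' at-home typing, `"HOME"`). Key content is never stored; each keystroke
#' carries only a coarse category -- `"LEFT"`, `"RIGHT"` or `"SPECIAL"` --
#' which is all the downstream analysis needs (special keys such as SHIFT
#' engage nonstandard digit kinematics and are excluded from hold-time
#' extraction).
#'
#' All timestamps are epoch-relative seconds; millisecond quantities appear
#' only in formatted reports.
#'
#' @param subject_id Opaque subject identifier (single string).
#' @param setting `"CLINIC"` or `"HOME"`.
#' @param events A data.frame with numeric columns `press_time` and
#'   `release_time` (seconds) and character column `key_category`
#'   (`"LEFT"`, `"RIGHT"` or `"SPECIAL"`). Rows are sorted by `press_time`
#'   on construction.
#' @param group_label Optional clinical group, `"PD"` or `"CONTROL"`.
#' @param updrs_iii Optional UPDRS-III motor score, integer in 0--108.
#'
#' @return An object of class `subject_log`: a list with elements
#'   `subject_id`, `setting`, `events`, `group_label`, `updrs_iii`.
#' @export
subject_log <- function(subject_id, setting, events,
                        group_label = NULL, updrs_iii = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!setting %in% c("CLINIC", "HOME")) {
    stop_nqi("setting must be 'CLINIC' or 'HOME', got '%s'", setting)
  }
  req <- c("press_time", "release_time", "key_category")
  if (!all(req %in% names(events))) {
    stop_nqi("events missing required column(s): %s",
             paste(setdiff(req, names(events)), collapse = ", "))
  }
  events <- events[req]
  bad_cat <- !events$key_category %in% c("LEFT", "RIGHT", "SPECIAL")
  if (any(bad_cat)) {
    stop_nqi("invalid key_category at event(s) %s",
             paste(utils::head(which(bad_cat), 5L), collapse = ", "))
  }
  neg <- which(events$release_time < events$press_time)
  if (length(neg)) {
    stop_nqi("release_time < press_time at event index %d (clock fault)", neg[1L])
  }
  if (is.unsorted(events$press_time)) {
    events <- events[order(events$press_time), , drop = FALSE]
  }
  rownames(events) <- NULL
  if (!is.null(group_label) && !group_label %in% c("PD", "CONTROL")) {
    stop_nqi("group_label must be 'PD' or 'CONTROL'")
  }
  if (!is.null(updrs_iii)) {
    updrs_iii <- as.integer(updrs_iii)
    if (is.na(updrs_iii) || updrs_iii < 0L || updrs_iii > 108L) {
      stop_nqi("updrs_iii must be an integer in [0, 108]")
    }
  }
  structure(
    list(subject_id = subject_id, setting = setting, events = events,
         group_label = group_label, updrs_iii = updrs_iii),
    class = "subject_log"
  )
}

#' @export
print.subject_log <- function(x, ...) {
  cat(sprintf("<subject_log> %s [%s]%s: %d keystrokes spanning %.1f s\n",
              x$subject_id, x$setting,
              if (is.null(x$group_label)) "" else paste0(" ", x$group_label),
              nrow(x$events),
              if (nrow(x$events)) diff(range(x$events$press_time)) else 0))
  invisible(x)
}

# CSV dialect: subject_id, setting (CLINIC|HOME), press_time, release_time,
# key_category (L|R|S); one row per keystroke, UTF-8, header required.
.cat_from_code <- c(L = "LEFT", R = "RIGHT", S = "SPECIAL")
.code_from_cat <- c(LEFT = "L", RIGHT = "R", SPECIAL = "S")

#' Read a keystroke log file
#'
#' Parses the keystroke-log CSV dialect (columns `subject_id`, `setting`,
#' `press_time`, `release_time`, `key_category` coded `L`/`R`/`S`) into one
#' [subject_log()] per `(subject_id, setting)` pair. Rows whose release
#' precedes their press indicate clock faults and are rejected with a
#' per-row warning rather than clamped.
#'
#' @param path Path to a CSV file in the keystroke-log dialect.
#' @return A list of `subject_log` objects, one per `(subject_id, setting)`
#'   pair, each with events sorted by press time.
#' @export
read_keystroke_log <- function(path) {
  if (!file.exists(path)) stop_nqi("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("subject_id", "setting", "press_time", "release_time", "key_category")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop_nqi("keystroke log format error: missing column(s) %s",
             paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warn_nqi("empty keystroke log: %s", path)
    return(list())
  }
  press <- suppressWarnings(as.numeric(raw$press_time))
  release <- suppressWarnings(as.numeric(raw$release_time))
  bad <- which(is.na(press) | is.na(release))
  if (length(bad)) {
    # +1 for the header line so the number matches the file
    stop_nqi("unparseable timestamp at line %d of %s", bad[1L] + 1L, path)
  }
  cat_full <- .cat_from_code[raw$key_category]
  if (anyNA(cat_full)) {
    stop_nqi("unknown key_category code at line %d of %s (expected L/R/S)",
             which(is.na(cat_full))[1L] + 1L, path)
  }
  clock_fault <- release < press
  if (any(clock_fault)) {
    warn_nqi("rejected %d row(s) with release < press (lines %s)",
             sum(clock_fault),
             paste(utils::head(which(clock_fault) + 1L, 10L), collapse = ", "))
  }
  keep <- !clock_fault
  df <- data.frame(subject_id = raw$subject_id[keep],
                   setting = raw$setting[keep],
                   press_time = press[keep],
                   release_time = release[keep],
                   key_category = unname(cat_full[keep]),
                   stringsAsFactors = FALSE)
  key <- interaction(df$subject_id, df$setting, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(d) {
    subject_log(d$subject_id[1L], d$setting[1L],
                d[c("press_time", "release_time", "key_category")])
  })
  names(out) <- NULL
  out
}

#' Write subject logs to the keystroke-log CSV dialect
#'
#' @param logs A `subject_log` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_keystroke_log <- function(logs, path) {
  if (inherits(logs, "subject_log")) logs <- list(logs)
  rows <- lapply(logs, function(log) {
    ev <- log$events
    data.frame(subject_id = log$subject_id, setting = log$setting,
               press_time = ev$press_time, release_time = ev$release_time,
               key_category = unname(.code_from_cat[ev$key_category]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write cohort metadata
#'
#' Cohort metadata CSV: columns `subject_id`, `group` (`PD`|`CONTROL`) and
#' `updrs_iii` (integer or empty).
#'
#' @param path CSV path.
#' @return A data.frame with columns `subject_id`, `group`, `updrs_iii`.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop_nqi("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group")
  if (!all(req %in% names(df))) {
    stop_nqi("metadata format error: missing column(s) %s",
             paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (!"updrs_iii" %in% names(df)) df$updrs_iii <- NA_integer_
  df$updrs_iii <- suppressWarnings(as.integer(df$updrs_iii))
  df[c("subject_id", "group", "updrs_iii")]
}

#' @rdname read_cohort_metadata
#' @param metadata Data.frame as returned by [read_cohort_metadata()].
#' @export
write_cohort_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hold-time series of a subject log
#'
#' Hold time (HT) is the interval between pressing and releasing a single
#' key -- the basic signal of the analysis. Keystrokes in the `SPECIAL`
#' category (SHIFT and friends) engage nonstandard digit kinematics and
#' contribute nothing.
#'
#' @param log A [subject_log()].
#' @return An object of class `ht_series`: list with numeric vectors
#'   `times` (press time of each retained keystroke, seconds) and `values`
#'   (release - press, seconds), equal length.
#' @export
compute_hold_times <- function(log) {
  stopifnot(inherits(log, "subject_log"))
  ev <- log$events
  neg <- which(ev$release_time < ev$press_time)
  if (length(neg)) {
    stop_nqi("release_time < press_time at event index %d", neg[1L])
  }
  keep <- ev$key_category != "SPECIAL"
  structure(list(times = ev$press_time[keep],
                 values = ev$release_time[keep] - ev$press_time[keep]),
            class = "ht_series")
}

#' Flight-time series of a subject log
#'
#' Flight time (FT) is the delay between two consecutive key presses. Pairs
#' spanning a pause longer than `max_gap` are omitted so session boundaries
#' and multi-hour breaks do not enter the FT distribution.
#'
#' @param log A [subject_log()].
#' @param max_gap Longest press-to-press delay (seconds) still counted as a
#'   flight time. Default 5.
#' @return An object of class `ft_series`: list with `times` (press time of
#'   the later keystroke of each retained pair) and `values` (delays,
#'   seconds).
#' @export
compute_flight_times <- function(log, max_gap = 5) {
  stopifnot(inherits(log, "subject_log"), max_gap > 0)
  p <- log$events$press_time
  if (length(p) < 2L) {
    return(structure(list(times = numeric(0), values = numeric(0)),
                     class = "ft_series"))
  }
  d <- diff(p)
  keep <- d <= max_gap
  structure(list(times = p[-1L][keep], values = d[keep]), class = "ft_series")
}

#' Raw typing metrics for one subject
#'
#' Median hold time and median flight time, the two raw metrics used in the
#' cross-setting correlation analysis. The even-length median is the mean of
#' the two central order statistics (the [stats::median()] convention).
#'
#' @inheritParams compute_flight_times
#' @return Named list `median_ht`, `median_ft` (seconds).
#' @export
subject_raw_metrics <- function(log, max_gap = 5) {
  ht <- compute_hold_times(log)
  ft <- compute_flight_times(log, max_gap = max_gap)
  if (length(ht$values) == 0L || length(ft$values) == 0L) {
    stop_nqi("insufficient data for raw metrics of subject '%s' (%d HT, %d FT)",
             log$subject_id, length(ht$values), length(ft$values))
  }
  list(median_ht = stats::median(ht$values),
       median_ft = stats::median(ft$values))
}

#' Restrict a subject log to a baseline interval
#'
#' Drops events outside `[start, end)`. Baseline trimming (e.g. the 7-day
#' at-home rule, or truncation at a medication change) is an input-preparation
#' step applied before windowing.
#'
#' @param log A [subject_log()].
#' @param start,end Interval bounds in seconds (half-open).
#' @return A trimmed `subject_log`.
#' @export
trim_baseline <- function(log, start, end) {
  stopifnot(inherits(log, "subject_log"), end > start)
  keep <- log$events$press_time >= start & log$events$press_time < end
  subject_log(log$subject_id, log$setting,
              log$events[keep, , drop = FALSE],
              group_label = log$group_label, updrs_iii = log$updrs_iii)
}
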