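#' Segment a hold-time series into non-overlapping typing windows
#'
#' The hold-time signal is split by non-overlapping fixed-length windows
#' (default 90 s) that downstream stages treat as independent typing units.
#' The grid is anchored at the first keystroke of the series and bins are
#' half-open, `[t0 + k*L, t0 + (k+1)*L)`, so every keystroke belongs to
#' exactly one bin; empty bins are omitted. Anchoring at the first keystroke
#' makes the segmentation deterministic and independent of absolute clock
#' origin.
#'
#' @param series An `ht_series` from [compute_hold_times()].
#' @param window_length Window length in seconds (default 90).
#' @return List of `typing_window` objects; each a list with
#'   `window_start`, `window_length`, `ht_values` and `keystroke_count`.
#' @export
segment_windows <- function(series, window_length = 90) {
  stopifnot(inherits(series, "ht_series"), window_length > 0)
  n <- length(series$times)
  if (n == 0L) return(list())
  t0 <- series$times[1L]
  bin <- floor((series$times - t0) / window_length)
  idx <- split(seq_len(n), bin)
  ks <- as.numeric(names(idx))
  out <- mapply(function(i, k) {
    structure(list(window_start = t0 + k * window_length,
                   window_length = window_length,
                   ht_values = series$values[i],
                   keystroke_count = length(i)),
              class = "typing_window")
  }, idx, ks, SIMPLIFY = FALSE)
  names(out) <- NULL
  out
}

#' Keep only valid typing windows
#'
#' A valid window contains at least `min_keystrokes` keystrokes (default 30)
#' within its interval; windows below the threshold are typing gaps or
#' low-activity stretches and are discarded. Order is preserved.
#'
#' @param windows List of `typing_window` objects.
#' @param min_keystrokes Validity threshold, default 30.
#' @return The sublist of windows with `keystroke_count >= min_keystrokes`.
#' @export
filter_valid <- function(windows, min_keystrokes = 30) {
  stopifnot(min_keystrokes >= 1)
  windows[vapply(windows, function(w) w$keystroke_count >= min_keystrokes,
                 logical(1))]
}

#' Typing-activity summary for one hold-time series
#'
#' Counts valid windows overall and per calendar day (day index =
#' `floor((window_start - t_origin) / 86400)` relative to the subject's
#' first event). Active minutes are `valid_window_count * window_length/60`,
#' so with the defaults 10 valid windows correspond exactly to the 15-minute
#' active-typing threshold.
#'
#' @inheritParams segment_windows
#' @inheritParams filter_valid
#' @return List with `valid_window_count`, `active_minutes` and
#'   `per_day_counts` (named integer vector, names are day indices).
#' @export
activity_summary <- function(series, window_length = 90, min_keystrokes = 30) {
  windows <- filter_valid(segment_windows(series, window_length), min_keystrokes)
  k <- length(windows)
  if (k == 0L) {
    return(list(valid_window_count = 0L, active_minutes = 0,
                per_day_counts = integer(0)))
  }
  t0 <- series$times[1L]
  starts <- vapply(windows, `[[`, numeric(1), "window_start")
  day <- floor((starts - t0) / 86400)
  per_day <- table(day)
  list(valid_window_count = k,
       active_minutes = k * window_length / 60,
       per_day_counts = stats::setNames(as.integer(per_day), names(per_day)))
}

#' Partition a cohort by the minimum-activity eligibility rule
#'
#' Subjects must aggregate at least `min_valid_windows` valid windows
#' (default 10, i.e. 15 minutes of active typing) to enter the analysis;
#' the rest are excluded with a logged reason.
#'
#' @param cohort List of [subject_log()] objects (typically the HOME logs of
#'   a baseline period).
#' @param min_valid_windows Eligibility threshold, default 10.
#' @inheritParams activity_summary
#' @return List with elements `included` and `excluded` (lists of
#'   `subject_log`) and `exclusion_log` (data.frame `subject_id`,
#'   `valid_window_count`, `reason`).
#' @export
eligibility_filter <- function(cohort, min_valid_windows = 10,
                               window_length = 90, min_keystrokes = 30) {
  stopifnot(min_valid_windows >= 1)
  counts <- vapply(cohort, function(log) {
    activity_summary(compute_hold_times(log), window_length,
                     min_keystrokes)$valid_window_count
  }, integer(1))
  ok <- counts >= min_valid_windows
  excluded_ids <- vapply(cohort[!ok], `[[`, character(1), "subject_id")
  list(
    included = cohort[ok],
    excluded = cohort[!ok],
    exclusion_log = data.frame(
      subject_id = excluded_ids,
      valid_window_count = counts[!ok],
      reason = if (length(excluded_ids)) {
        sprintf("below %d-valid-window activity threshold", min_valid_windows)
      } else character(0),
      stringsAsFactors = FALSE)
  )
}
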