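# Named registry of window feature sets. A feature set is a function
# (ht_values, config) -> named numeric vector of fixed length; registering
# alternatives lets the window->vector reduction be swapped without touching
# the model layer.
.feature_registry <- new.env(parent = emptyenv())

#' Register a window feature set
#'
#' @param name Registry key.
#' @param fn Function `(ht_values, config)` returning a named numeric vector
#'   of constant length for any input of >= 2 values.
#' @export
register_feature_set <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

#' @rdname register_feature_set
#' @export
list_feature_sets <- function() ls(.feature_registry)

get_feature_set <- function(name) {
  if (!exists(name, envir = .feature_registry, inherits = FALSE)) {
    stop_nqi("unknown feature set '%s' (registered: %s)", name,
             paste(list_feature_sets(), collapse = ", "))
  }
  get(name, envir = .feature_registry)
}

nqi7_feature_names <- c("ht_mean", "ht_sd", "ht_cv", "ht_iqr",
                        "ht_masd", "ht_heavy_frac", "ht_capped_sd")

# Default variance-centric 7-component reduction of a window's hold times:
#   1 mean, 2 sample SD, 3 coefficient of variation, 4 interquartile range,
#   5 mean absolute lag-1 successive difference, 6 fraction of holds above
#   2x the window median, 7 sample SD after discarding holds above the
#   outlier cap (implausibly long holds treated as pauses, default 0.5 s).
nqi7_default <- function(ht, config = list()) {
  cap <- config$outlier_cap_s %||% 0.5
  m <- mean(ht)
  s <- stats::sd(ht)
  capped <- ht[ht <= cap]
  c(ht_mean = m,
    ht_sd = s,
    ht_cv = if (m > 0) s / m else 0,
    ht_iqr = unname(stats::quantile(ht, 0.75) - stats::quantile(ht, 0.25)),
    ht_masd = mean(abs(diff(ht))),
    ht_heavy_frac = mean(ht > 2 * stats::median(ht)),
    ht_capped_sd = if (length(capped) >= 2L) stats::sd(capped) else 0)
}

#' Reduce a typing window to its feature vector
#'
#' Applies the registered feature set (default `"nqi7_default"`, the
#' 7-component variance-centric reduction documented in the package
#' vignette) to the hold times of one window.
#'
#' @param window A `typing_window` from [segment_windows()].
#' @param feature_set Registry name, default `"nqi7_default"`.
#' @param config List of feature-set options; the default set understands
#'   `outlier_cap_s` (seconds, default 0.5).
#' @return Named numeric vector (length 7 for the default set).
#' @export
window_features <- function(window, feature_set = "nqi7_default",
                            config = list()) {
  ht <- window$ht_values
  if (length(ht) < 2L) {
    stop_nqi("degenerate window at t=%.1f: %d keystroke(s), need >= 2",
             window$window_start %||% NA_real_, length(ht))
  }
  v <- get_feature_set(feature_set)(ht, config)
  if (any(!is.finite(v))) {
    stop_nqi("non-finite feature component(s): %s",
             paste(names(v)[!is.finite(v)], collapse = ", "))
  }
  v
}

#' Feature matrix of a list of windows
#'
#' @param windows List of `typing_window` objects (usually already passed
#'   through [filter_valid()]).
#' @inheritParams window_features
#' @return Numeric matrix, one row per window.
#' @export
feature_matrix <- function(windows, feature_set = "nqi7_default",
                           config = list()) {
  if (!length(windows)) {
    return(matrix(numeric(0), nrow = 0,
                  ncol = length(nqi7_feature_names),
                  dimnames = list(NULL, nqi7_feature_names)))
  }
  do.call(rbind, lapply(windows, window_features,
                        feature_set = feature_set, config = config))
}

#' Fit / apply a z-score feature normalizer
#'
#' Standardizes each feature component with the training-set mean and
#' sample SD. Components that are constant in training are flagged and
#' mapped to 0 (they carry no information for the regressors).
#'
#' @param training_features Numeric matrix of training window features
#'   (rows = windows).
#' @return `fit_feature_normalizer`: object of class `nqi_normalizer` with
#'   elements `center`, `scale`, `constant`.
#' @export
fit_feature_normalizer <- function(training_features) {
  x <- as.matrix(training_features)
  if (nrow(x) < 2L) stop_nqi("need >= 2 training windows to fit a normalizer")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  constant <- scale == 0 | !is.finite(scale)
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "nqi_normalizer")
}

#' @rdname fit_feature_normalizer
#' @param normalizer An `nqi_normalizer`.
#' @param features Numeric vector or matrix of raw features.
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "nqi_normalizer"))
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(x) != length(normalizer$center)) {
    stop_nqi("feature dimension %d does not match normalizer dimension %d",
             ncol(x), length(normalizer$center))
  }
  z <- sweep(sweep(x, 2L, normalizer$center), 2L, normalizer$scale, "/")
  z[, normalizer$constant] <- 0
  if (is.matrix(features)) z else stats::setNames(drop(z), names(normalizer$center))
}

register_feature_set("nqi7_default", nqi7_default)
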