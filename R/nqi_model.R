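#' Train the ensemble of linear support-vector regressors
#'
#' The scoring model is a family of linear epsilon-insensitive SVRs, each
#' member fit on the pooled windows of a subject-level bootstrap resample of
#' the training cohort (subjects resampled with replacement, keeping each
#' resampled subject's windows together, which preserves the independence
#' structure of the data). Features are z-scored with statistics from the
#' full training set. The regression target is the subject's numeric label
#' (0 control / 1 PD) or, optionally, the UPDRS-III motor score scaled to
#' \[0, 1\].
#'
#' @param features_by_subject Named list: one numeric feature matrix (rows =
#'   valid windows) per subject.
#' @param labels Named numeric vector (0 = control, 1 = PD) covering the same
#'   subjects.
#' @param n_members Ensemble size, default 50.
#' @param cost SVR regularization constant C, default 1.
#' @param epsilon Width of the epsilon-insensitive tube, default 0.1.
#' @param target `"binary"` (default) regresses onto the 0/1 group label;
#'   `"updrs_normalized"` regresses onto `updrs/108` supplied via `updrs`.
#' @param updrs Named numeric vector of UPDRS-III scores, required when
#'   `target = "updrs_normalized"`.
#' @param seed Integer seed controlling the bootstrap resamples; training is
#'   bit-reproducible given the seed.
#' @return Object of class `nqi_ensemble`: list with `weights` (n_members x
#'   p matrix), `intercepts`, `normalizer`, `n_members`, `feature_names`,
#'   and `training_meta` (seed, hyperparameters, cohort sizes, resample
#'   indices).
#' @export
train_ensemble <- function(features_by_subject, labels, n_members = 50,
                           cost = 1, epsilon = 0.1,
                           target = c("binary", "updrs_normalized"),
                           updrs = NULL, seed = 1L) {
  target <- match.arg(target)
  ids <- names(features_by_subject)
  if (is.null(ids) || is.null(names(labels))) {
    stop_nqi("features_by_subject and labels must be named by subject id")
  }
  labels <- labels[ids]
  if (anyNA(labels)) stop_nqi("missing label for some training subjects")
  if (length(unique(labels)) < 2L) {
    stop_nqi("training cohort contains a single class; need both controls and PD")
  }
  if (any(table(labels) < 2L)) {
    stop_nqi("need >= 2 training subjects per class")
  }
  n_windows <- vapply(features_by_subject, nrow, integer(1))
  if (any(n_windows < 1L)) {
    stop_nqi("subject(s) without valid windows: %s",
             paste(ids[n_windows < 1L], collapse = ", "))
  }
  y_subject <- if (target == "binary") {
    labels
  } else {
    if (is.null(updrs)) stop_nqi("target 'updrs_normalized' requires updrs scores")
    u <- updrs[ids]
    if (anyNA(u)) stop_nqi("missing UPDRS-III score for some training subjects")
    u / 108
  }

  pooled <- do.call(rbind, features_by_subject)
  const <- apply(pooled, 2L, function(v) stats::sd(v) == 0)
  if (all(const)) {
    stop_nqi("all feature components are constant in training: %s",
             paste(colnames(pooled), collapse = ", "))
  }
  if (any(const)) {
    warn_nqi("constant training feature component(s) mapped to 0: %s",
             paste(colnames(pooled)[const], collapse = ", "))
  }
  normalizer <- fit_feature_normalizer(pooled)

  p <- ncol(pooled)
  weights <- matrix(NA_real_, n_members, p,
                    dimnames = list(NULL, colnames(pooled)))
  intercepts <- numeric(n_members)
  resamples <- vector("list", n_members)
  n_sub <- length(ids)
  for (m in seq_len(n_members)) {
    with_seed(sub_seed(seed, 101L, m), {
      repeat {
        take <- sample.int(n_sub, n_sub, replace = TRUE)
        if (length(unique(labels[take])) == 2L) break
      }
      resamples[[m]] <- take
    })
    x <- apply_normalizer(normalizer,
                          do.call(rbind, features_by_subject[take]))
    y <- rep(y_subject[take], times = n_windows[take])
    fit <- e1071::svm(x = x, y = y, type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    weights[m, ] <- drop(crossprod(fit$coefs, fit$SV))
    intercepts[m] <- -fit$rho
  }
  structure(
    list(weights = weights, intercepts = intercepts,
         normalizer = normalizer, n_members = n_members,
         feature_names = colnames(pooled),
         training_meta = list(seed = as.integer(seed), cost = cost,
                              epsilon = epsilon, target = target,
                              n_pd = sum(labels == 1),
                              n_control = sum(labels == 0),
                              resample_indices = resamples)),
    class = "nqi_ensemble"
  )
}

#' @export
print.nqi_ensemble <- function(x, ...) {
  cat(sprintf(
    "<nqi_ensemble> %d linear SVR members, %d features; trained on %d PD / %d control subjects (seed %d)\n",
    x$n_members, length(x$feature_names), x$training_meta$n_pd,
    x$training_meta$n_control, x$training_meta$seed))
  invisible(x)
}

#' Score a single typing window
#'
#' The window-level score is the median over ensemble members of the linear
#' response `w . x + b` on the normalized feature vector.
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param features Raw (unnormalized) feature vector of one window.
#' @return Scalar window score.
#' @export
score_window <- function(ensemble, features) {
  drop(score_windows(ensemble, matrix(features, nrow = 1)))
}

#' @rdname score_window
#' @param feature_mat Matrix of raw feature vectors (rows = windows).
#' @return `score_windows`: numeric vector of per-window scores.
#' @export
score_windows <- function(ensemble, feature_mat) {
  stopifnot(inherits(ensemble, "nqi_ensemble"))
  if (ncol(feature_mat) != ncol(ensemble$weights)) {
    stop_nqi("feature dimension %d does not match model dimension %d",
             ncol(feature_mat), ncol(ensemble$weights))
  }
  z <- apply_normalizer(ensemble$normalizer, feature_mat)
  member_out <- z %*% t(ensemble$weights)          # windows x members
  member_out <- sweep(member_out, 2L, ensemble$intercepts, "+")
  apply(member_out, 1L, stats::median)
}

#' Compute a subject's nQi
#'
#' The nQi is the arithmetic mean of the window-level scores over the
#' subject's valid windows; higher values indicate more PD-like typing.
#'
#' @inheritParams score_windows
#' @param subject_id,setting Identification carried into the result.
#' @param min_valid_windows Warn (not error) below this count, default 10.
#' @return Object of class `nqi_result`: list with `subject_id`, `setting`,
#'   `window_scores`, `nqi`, `n_valid_windows`.
#' @export
score_subject <- function(ensemble, feature_mat, subject_id,
                          setting = "CLINIC", min_valid_windows = 10) {
  if (is.null(dim(feature_mat)) || nrow(feature_mat) == 0L) {
    stop_nqi("insufficient data: no valid windows for subject '%s'", subject_id)
  }
  if (nrow(feature_mat) < min_valid_windows) {
    warn_nqi("subject '%s' has only %d valid window(s) (< %d); nQi will be noisy",
             subject_id, nrow(feature_mat), min_valid_windows)
  }
  ws <- score_windows(ensemble, feature_mat)
  structure(list(subject_id = subject_id, setting = setting,
                 window_scores = ws, nqi = mean(ws),
                 n_valid_windows = length(ws)),
            class = "nqi_result")
}

#' @export
print.nqi_result <- function(x, ...) {
  cat(sprintf("<nqi_result> %s [%s]: nQi = %.4f over %d valid windows\n",
              x$subject_id, x$setting, x$nqi, x$n_valid_windows))
  invisible(x)
}

#' Closest-to-(0,1) classification cutoff
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' sorted scores, plus -Inf and +Inf) and returns the one whose ROC point
#' minimizes the Euclidean distance to the perfect-classifier corner (0, 1).
#' The classification rule is `score >= threshold` implies PD. Ties are
#' broken toward the smaller threshold (higher sensitivity).
#'
#' @param scores Numeric subject scores.
#' @param labels 0/1 labels (1 = PD).
#' @return List `threshold`, `sensitivity`, `specificity`, `distance`,
#'   `degenerate` (TRUE when all scores are identical).
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_nqi("scores/labels length mismatch")
  if (length(unique(labels)) < 2L) {
    stop_nqi("cutoff selection requires both classes")
  }
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(cand, function(th) mean(pos >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(neg < th), numeric(1))
  d <- sqrt((1 - sens)^2 + (1 - spec)^2)
  i <- which(d == min(d))[1L]   # ties -> smaller threshold, higher sensitivity
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i],
       distance = d[i], degenerate = length(s) == 1L)
}

#' Serialize / restore a trained ensemble
#'
#' Versioned JSON holding member weights and intercepts, normalizer
#' statistics and training metadata; restoring reproduces scoring
#' bit-for-bit (full-precision floats).
#'
#' @param ensemble A trained `nqi_ensemble`.
#' @param path Output JSON path.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "nqi_ensemble"))
  obj <- list(
    format = "nqi_ensemble", version = 1L,
    feature_names = ensemble$feature_names,
    weights = lapply(seq_len(ensemble$n_members),
                     function(i) unname(ensemble$weights[i, ])),
    intercepts = ensemble$intercepts,
    normalizer = list(center = unname(ensemble$normalizer$center),
                      scale = unname(ensemble$normalizer$scale),
                      constant = unname(ensemble$normalizer$constant)),
    training_meta = ensemble$training_meta[
      c("seed", "cost", "epsilon", "target", "n_pd", "n_control")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nqi_ensemble")) {
    stop_nqi("not an nqi_ensemble file: %s", path)
  }
  w <- if (is.matrix(obj$weights)) obj$weights else
    do.call(rbind, lapply(obj$weights, as.numeric))
  dimnames(w) <- list(NULL, obj$feature_names)
  normalizer <- structure(
    list(center = stats::setNames(obj$normalizer$center, obj$feature_names),
         scale = stats::setNames(obj$normalizer$scale, obj$feature_names),
         constant = stats::setNames(as.logical(obj$normalizer$constant),
                                    obj$feature_names)),
    class = "nqi_normalizer")
  structure(
    list(weights = w, intercepts = as.numeric(obj$intercepts),
         normalizer = normalizer, n_members = nrow(w),
         feature_names = obj$feature_names,
         training_meta = obj$training_meta),
    class = "nqi_ensemble")
}
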