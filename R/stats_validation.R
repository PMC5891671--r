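#' ROC curve and AUC
#'
#' The AUC is the probability that a randomly chosen positive subject scores
#' higher than a randomly chosen negative one; ties count one half. It is
#' computed by the rank (Mann-Whitney) identity, which equals
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`. The curve is a threshold
#' sweep over the observed scores: each distinct score, taken as the rule
#' `score >= threshold => positive`, contributes one
#' (1 - specificity, sensitivity) point.
#'
#' @param scores Numeric scores, higher = more PD-like.
#' @param labels 0/1 labels (1 = PD).
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `sensitivity`, ordered from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_nqi("scores/labels length mismatch")
  if (length(unique(labels)) < 2L) stop_nqi("ROC requires both classes")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores)   # midranks handle ties -> 0.5 credit per tied pair
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Bootstrap ROC analysis
#'
#' Subjects are resampled with replacement `n_boot` times; each resample
#' yields an AUC. The headline AUC is the mean of the bootstrap AUC
#' distribution (the "average result of the bootstrapped ROC analysis"),
#' with the empirical 5th and 95th percentiles as the confidence interval.
#' The full-sample AUC is also reported. Resamples that lose a class are
#' redrawn (counted); a resampling process needing more than `n_boot / 2`
#' redraws is treated as degenerate and aborts.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples, default 1000 (values below
#'   100 trigger a warning).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Object of class `roc_result`: `auc` (bootstrap mean),
#'   `auc_point` (full sample), `ci_lower`, `ci_upper` (5th/95th
#'   percentiles), `curve`, `threshold`, `sensitivity`, `specificity`
#'   (closest-to-(0,1) cutoff on the full sample), `n_boot`, `n_redraws`.
#' @export
bootstrap_roc <- function(scores, labels, n_boot = 1000, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop_nqi("ROC requires both classes")
  if (n_boot < 100) warn_nqi("n_boot = %d is below 100; CIs will be coarse", n_boot)
  n <- length(scores)
  full <- roc_auc(scores, labels)
  aucs <- numeric(n_boot)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        take <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[take])) == 2L) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > n_boot / 2) {
          stop_nqi("persistent single-class resamples (%d redraws)", n_redraws)
        }
      }
      aucs[b] <- roc_auc(scores[take], labels[take])$auc
    }
  })
  cut <- select_cutoff(scores, labels)
  structure(
    list(auc = mean(aucs), auc_point = full$auc,
         ci_lower = unname(stats::quantile(aucs, 0.05)),
         ci_upper = unname(stats::quantile(aucs, 0.95)),
         curve = full$curve,
         threshold = cut$threshold, sensitivity = cut$sensitivity,
         specificity = cut$specificity,
         n_boot = n_boot, n_redraws = n_redraws, seed = as.integer(seed)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (bootstrap mean of %d; 5th-95th %.3f-%.3f; point %.3f)\n  cutoff %.4f -> sensitivity %.2f / specificity %.2f\n",
    x$auc, x$n_boot, x$ci_lower, x$ci_upper, x$auc_point,
    x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of the null hypothesis that the two groups come
#' from the same distribution. The U statistic counts pairs where a value
#' of `group_a` exceeds one of `group_b` (ties half). Small balanced
#' samples without ties (`min(n, m) <= 8`) use the exact permutation
#' distribution; otherwise the normal approximation with continuity and tie
#' correction is used. Both paths are delegated to [stats::wilcox.test()].
#'
#' @param group_a,group_b Numeric vectors.
#' @return List `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop_nqi("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- min(length(group_a), length(group_b)) <= 8L && !ties
  ht <- stats::wilcox.test(group_a, group_b, exact = exact,
                           correct = TRUE, alternative = "two.sided")
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

# Placement values ("structural components") of the DeLong construction:
# V10_i averages psi(X_i, Y_.) over negatives for each positive, V01_j
# averages psi(X_., Y_j) over positives for each negative (psi = 1 if the
# positive wins, 1/2 on ties); both have mean equal to the AUC.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs obtained from two score vectors measured on the *same*
#' subjects (paired design: one cohort scored in two settings). The
#' variance of the AUC difference is estimated from the covariance of the
#' placement-value structural components, and the difference is referred to
#' a standard normal.
#'
#' @param scores_a,scores_b Paired score vectors (same subjects, same order).
#' @param labels Shared 0/1 labels.
#' @return List `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`, `degenerate`
#'   (TRUE when the difference has zero estimated variance, in which case
#'   `p_value` is 1).
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop_nqi("paired DeLong requires equal-length score and label vectors")
  }
  if (length(unique(labels)) < 2L) stop_nqi("DeLong requires both classes")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m < 2L || n < 2L) {
    warn_nqi("DeLong variance needs >= 2 subjects per class (have %d/%d); returning degenerate result", m, n)
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                var_diff = NA_real_, degenerate = TRUE))
  }
  s10 <- stats::cov(cbind(pa$v10, pb$v10))   # over positives
  s01 <- stats::cov(cbind(pa$v01, pb$v01))   # over negatives
  v <- s10 / m + s01 / n                     # 2x2 covariance of (auc_a, auc_b)
  var_diff <- v[1, 1] + v[2, 2] - 2 * v[1, 2]
  if (var_diff <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                var_diff = var_diff, degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = var_diff,
       degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between paired measurements via the mean difference
#' `d`, its sample SD, and the limits of agreement `d +/- 1.96 * SDd`. The
#' fraction of pairs whose difference falls inside the closed LoA interval
#' is also reported (about 0.95 for Gaussian differences).
#'
#' @param x,y Equal-length paired numeric vectors (differences are `x - y`).
#' @return List `bias_d`, `sd_d`, `loa_lower`, `loa_upper`,
#'   `fraction_within_loa`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_nqi("paired vectors must have equal length")
  if (length(x) < 2L) stop_nqi("Bland-Altman requires n >= 2")
  d <- x - y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  lo <- bias - 1.96 * sd_d
  hi <- bias + 1.96 * sd_d
  list(bias_d = bias, sd_d = sd_d, loa_lower = lo, loa_upper = hi,
       fraction_within_loa = mean(d >= lo & d <= hi), n = length(d))
}

#' Line of best fit and correlation
#'
#' Pearson correlation (optionally Spearman) together with the ordinary
#' least-squares slope and intercept of `y` on `x`.
#'
#' @param x,y Paired numeric vectors, `n >= 3`; `x` must have non-zero
#'   variance.
#' @param method `"pearson"` (default) or `"spearman"` for the correlation
#'   coefficient; the fitted line is always ordinary least squares.
#' @return List `r`, `slope`, `intercept`, `method`.
#' @export
correlation_fit <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_nqi("paired vectors must have equal length")
  if (length(x) < 3L) stop_nqi("correlation_fit requires n >= 3")
  if (stats::sd(x) == 0) stop_nqi("zero variance in x; line of best fit undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = stats::cor(x, y, method = method),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       method = method)
}

#' Percentage agreement of two binary classifications
#'
#' The percentage of subjects receiving the same class under both settings
#' (each classification produced with its own setting's cutoff).
#'
#' @param class_a,class_b Equal-length binary (0/1 or logical) vectors.
#' @return Percent agreement in \[0, 100\].
#' @export
percentage_agreement <- function(class_a, class_b) {
  if (length(class_a) != length(class_b)) {
    stop_nqi("classification vectors must have equal length")
  }
  if (!length(class_a)) stop_nqi("empty classification vectors")
  100 * mean(as.integer(class_a) == as.integer(class_b))
}
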