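# brute-force AUC over all positive x negative pairs
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("AUC equals brute-force pair enumeration, with ties at one half", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  for (seed in 1:4) {
    withr::with_seed(seed, {
      s <- round(rnorm(12), 1)
      y <- rep(c(0, 1), 6)
    })
    expect_equal(roc_auc(s, y)$auc, pair_auc(s, y))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1) and consistent with the cutoff", {
  withr::with_seed(22, {
    s <- c(rnorm(15, 1), rnorm(15))
    y <- rep(c(1, 0), each = 15)
  })
  curve <- roc_auc(s, y)$curve
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_equal(curve$fpr[1], 0); expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  # the cutoff's attained operating point lies on the curve
  cut <- select_cutoff(s, y)
  i <- which(curve$threshold <= cut$threshold)[1] - 1L
  on_curve <- any(abs(curve$fpr - (1 - cut$specificity)) < 1e-12 &
                    abs(curve$sensitivity - cut$sensitivity) < 1e-12)
  expect_true(on_curve)
})

test_that("AUC obeys the rank identity with the Mann-Whitney U statistic", {
  for (seed in 5:8) {
    withr::with_seed(seed, {
      a <- rnorm(9, 0.3)
      b <- rnorm(11)
    })
    u <- mann_whitney_u(a, b)$U
    auc <- roc_auc(c(a, b), rep(c(1, 0), c(9, 11)))$auc
    expect_equal(auc, u / (9 * 11))
  }
})

test_that("bootstrap ROC is seed-deterministic, brackets the point AUC, and is exact under separation", {
  sep <- bootstrap_roc(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3),
                       n_boot = 200, seed = 9L)
  expect_equal(sep$auc, 1)
  expect_equal(c(sep$ci_lower, sep$ci_upper), c(1, 1))

  withr::with_seed(31, {
    s <- c(rnorm(26, 0.8), rnorm(26))
  })
  y <- rep(c(1, 0), each = 26)
  r1 <- bootstrap_roc(s, y, n_boot = 1000, seed = 4L)
  r2 <- bootstrap_roc(s, y, n_boot = 1000, seed = 4L)
  expect_identical(c(r1$auc, r1$ci_lower, r1$ci_upper),
                   c(r2$auc, r2$ci_lower, r2$ci_upper))
  expect_true(r1$ci_lower <= r1$auc_point && r1$auc_point <= r1$ci_upper)
  expect_true(r1$ci_lower >= 0 && r1$ci_upper <= 1)
  expect_warning(bootstrap_roc(s, y, n_boot = 50, seed = 1L), "below 100")
})

test_that("Mann-Whitney p-values match exact enumeration for small samples", {
  # A = {1,2}, B = {3,4}: U = 0; 1 of C(4,2)=6 orderings is as extreme,
  # two-sided exact p = 2/6
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$method, "exact")

  expect_gte(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p_value, 0.99)

  # n = m = 7: normal approximation within 0.02 of full enumeration
  withr::with_seed(33, {
    a <- rnorm(7, 0.6)
    b <- rnorm(7)
  })
  approx_p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  pooled <- c(a, b)
  combos <- utils::combn(14, 7)
  u_obs <- sum(outer(a, b, ">"))
  u_all <- apply(combos, 2, function(idx) sum(outer(pooled[idx], pooled[-idx], ">")))
  exact_p <- mean(abs(u_all - 24.5) >= abs(u_obs - 24.5))  # 24.5 = n*m/2
  expect_lt(abs(approx_p - exact_p), 0.02)
  # and the wrapper's exact path agrees with the enumeration
  expect_equal(mann_whitney_u(a, b)$p_value, exact_p, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("DeLong structural components match a direct placement computation on a hand-built example", {
  # 6 subjects, 3 positive (scores 3, 5, 7) and 3 negative (2, 5, 6)
  s <- c(3, 5, 7, 2, 5, 6)
  y <- c(1, 1, 1, 0, 0, 0)
  pl <- nqikit:::delong_placements(s, y)
  # positive placements: fraction of negatives each positive beats
  expect_equal(pl$v10, c((1 + 0 + 0) / 3, (1 + 0.5 + 0) / 3, 1))
  # negative placements: fraction of positives beating each negative
  expect_equal(pl$v01, c(1, (1 + 0.5 + 0) / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(pl$auc, pair_auc(s, y))
})

test_that("paired DeLong: identical scores give p = 1; antisymmetry in the two settings", {
  withr::with_seed(34, {
    s <- rnorm(20)
  })
  y <- rep(c(1, 0), 10)
  same <- delong_paired(s, s, y)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  withr::with_seed(35, {
    a <- rnorm(20, y)
    b <- rnorm(20, 0.5 * y)
  })
  ab <- delong_paired(a, b, y)
  ba <- delong_paired(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
})

test_that("paired DeLong agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(36, {
    y <- rep(c(1, 0), c(25, 27))
    lat <- rnorm(52, 0.9 * y)
    a <- lat + rnorm(52, sd = 0.6)
    b <- lat + rnorm(52, sd = 0.6)
  })
  mine <- delong_paired(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(mine$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
})

test_that("AUC and bootstrap CIs agree with pROC on a shared sample", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    s <- c(rnorm(20, 1), rnorm(20))
  })
  y <- rep(c(1, 0), each = 20)
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("Bland-Altman construction and the 95% interpretation of the LoA", {
  eq <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$bias_d, 0); expect_equal(eq$sd_d, 0)
  expect_equal(c(eq$loa_lower, eq$loa_upper), c(0, 0))
  expect_equal(eq$fraction_within_loa, 1)

  two <- bland_altman(c(0, 2), c(1, 1))     # differences -1, +1
  expect_equal(two$bias_d, 0)
  expect_equal(two$sd_d, sqrt(2))
  expect_equal(two$loa_upper, 1.96 * sqrt(2))
  expect_equal(two$loa_upper, 2.772, tolerance = 1e-3)

  withr::with_seed(38, {
    d <- rnorm(10000)
  })
  mc <- bland_altman(d, rep(0, 10000))
  expect_equal(mc$fraction_within_loa, 0.95, tolerance = 0.01)
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("correlation and line of best fit match closed-form expressions", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_fit(x, x),
               list(r = 1, slope = 1, intercept = 0, method = "pearson"),
               tolerance = 1e-12)
  fit2 <- correlation_fit(x, 2 * x + 1)
  expect_equal(fit2$r, 1); expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)

  withr::with_seed(39, {
    xr <- rnorm(20); yr <- 0.5 * xr + rnorm(20)
  })
  fit <- correlation_fit(xr, yr)
  sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  sxx <- sum((xr - mean(xr))^2)
  expect_equal(fit$slope, sxy / sxx)
  expect_equal(fit$intercept, mean(yr) - fit$slope * mean(xr))
  expect_equal(fit$r, sxy / sqrt(sxx * sum((yr - mean(yr))^2)))
  expect_error(correlation_fit(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("percentage agreement counts identical positions", {
  expect_equal(percentage_agreement(rep(1, 52), rep(1, 52)), 100)
  v <- rep(c(0, 1), 26)
  w <- v; w[5] <- 1 - w[5]
  expect_equal(percentage_agreement(v, w), 100 * 51 / 52)
  withr::with_seed(40, {
    a <- rbinom(31, 1, 0.5); b <- rbinom(31, 1, 0.5)
  })
  expect_equal(percentage_agreement(a, b), 100 * sum(a == b) / 31)
  expect_error(percentage_agreement(1:3, 1:4), "equal length")
})
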