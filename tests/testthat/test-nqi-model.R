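# hand-built ensemble for scoring tests: weights/intercepts set directly,
# identity normalizer
hand_ensemble <- function(weights, intercepts) {
  p <- ncol(weights)
  nz <- structure(list(center = rep(0, p), scale = rep(1, p),
                       constant = rep(FALSE, p)),
                  class = "nqi_normalizer")
  structure(list(weights = weights, intercepts = intercepts,
                 normalizer = nz, n_members = nrow(weights),
                 feature_names = paste0("f", seq_len(p)),
                 training_meta = list(seed = 0L)),
            class = "nqi_ensemble")
}

test_that("training is deterministic under a fixed seed and validates its inputs", {
  ts <- tiny_training_set()
  e1 <- train_ensemble(ts$features, ts$labels, n_members = 8, seed = 42L)
  e2 <- train_ensemble(ts$features, ts$labels, n_members = 8, seed = 42L)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$intercepts, e2$intercepts)
  e3 <- train_ensemble(ts$features, ts$labels, n_members = 8, seed = 43L)
  expect_false(identical(e1$weights, e3$weights))

  expect_error(train_ensemble(ts$features, stats::setNames(rep(1, 8), names(ts$labels)),
                              n_members = 4),
               "single class")
  one_each <- c(ts$features[1], ts$features[5])
  expect_error(train_ensemble(one_each, ts$labels[c(1, 5)], n_members = 4),
               ">= 2 training subjects")
  const_feats <- lapply(ts$features, function(m) m * 0 + 1)
  expect_error(train_ensemble(const_feats, ts$labels, n_members = 4),
               "constant")
})

test_that("trained scores separate a strongly structured synthetic training cohort", {
  # cohort sized like the external training set: 18 PD-like, 13 control-like
  ts <- tiny_training_set(n_pd = 18, n_ct = 13, windows = 8, seed = 7)
  ens <- train_ensemble(ts$features, ts$labels, n_members = 20, seed = 1L)
  nqi <- vapply(names(ts$labels), function(id) {
    suppressWarnings(score_subject(ens, ts$features[[id]], id)$nqi)
  }, numeric(1))
  expect_gte(roc_auc(nqi, ts$labels)$auc, 0.9)
  # direction: higher nQi for the PD-like group
  expect_gt(mean(nqi[ts$labels == 1]), mean(nqi[ts$labels == 0]))
})

test_that("window score is the median of member responses (dot-product oracle)", {
  # 3 members engineered to output 0.1, 0.5, 0.9 on x = (1, 1)
  w <- rbind(c(0.1, 0), c(0.5, 0), c(0, 0.9))
  ens <- hand_ensemble(w, c(0, 0, 0))
  expect_equal(score_window(ens, c(1, 1)), 0.5)

  single <- hand_ensemble(matrix(c(2, -1), 1), 0.25)
  expect_equal(score_window(single, c(0.3, 0.4)), 2 * 0.3 - 0.4 + 0.25)

  withr::with_seed(14, {
    W <- matrix(rnorm(15 * 7), 15)
    b <- rnorm(15)
    X <- matrix(rnorm(10 * 7), 10)
  })
  ens_r <- hand_ensemble(W, b)
  oracle <- apply(X, 1, function(x) median(W %*% x + b))
  expect_equal(score_windows(ens_r, X), oracle)
  expect_error(score_window(ens_r, c(1, 2)), "dimension")
})

test_that("nQi is the mean of window scores, invariant to order and duplication", {
  ens <- hand_ensemble(matrix(c(1, 0), 1), 0)   # score = first feature
  X <- cbind(c(0.0, 0.1, 0.2), 0)
  res <- suppressWarnings(score_subject(ens, X, "A"))
  expect_equal(res$nqi, 0.1)
  expect_equal(res$n_valid_windows, 3L)

  withr::with_seed(15, {
    X50 <- matrix(rnorm(50 * 2), 50)
  })
  r1 <- suppressWarnings(score_subject(ens, X50, "A"))
  r2 <- suppressWarnings(score_subject(ens, X50[sample(50), ], "A"))
  r3 <- suppressWarnings(score_subject(ens, rbind(X50, X50), "A"))
  expect_equal(r1$nqi, r2$nqi)
  expect_equal(r1$nqi, r3$nqi)
  expect_equal(r1$nqi, mean(score_windows(ens, X50)))

  expect_error(score_subject(ens, X50[0, , drop = FALSE], "A"), "insufficient")
  expect_warning(score_subject(ens, X50[1:3, ], "A"), "noisy")
})

test_that("closest-to-(0,1) cutoff matches exhaustive search and handles edge cases", {
  cut <- select_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cut$threshold, 0.5)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  tied <- select_cutoff(rep(0.3, 6), c(0, 0, 0, 1, 1, 1))
  expect_true(tied$degenerate)
  expect_equal(sort(c(tied$sensitivity, tied$specificity)), c(0, 1))

  withr::with_seed(16, {
    s <- round(rnorm(30), 2)                     # duplicates on purpose
    y <- rbinom(30, 1, plogis(2 * s))
  })
  if (length(unique(y)) == 2) {
    cut_r <- select_cutoff(s, y)
    # exhaustive oracle over a dense threshold sweep
    grid <- c(-Inf, sort(unique(c(s - 1e-6, s + 1e-6))), Inf)
    d <- vapply(grid, function(th) {
      sens <- mean(s[y == 1] >= th); spec <- mean(s[y == 0] < th)
      sqrt((1 - sens)^2 + (1 - spec)^2)
    }, numeric(1))
    expect_equal(cut_r$distance, min(d), tolerance = 1e-12)
  }
})

test_that("ensemble JSON serialization reproduces scoring bit-for-bit", {
  ts <- tiny_training_set()
  ens <- train_ensemble(ts$features, ts$labels, n_members = 6, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  X <- ts$features[[1]]
  expect_identical(score_windows(back, X), score_windows(ens, X))
  expect_equal(back$weights, ens$weights, tolerance = 0)
})

test_that("UPDRS-normalized regression target is accepted", {
  ts <- tiny_training_set()
  updrs <- stats::setNames(ifelse(ts$labels == 1, 22, 2), names(ts$labels))
  # epsilon must sit well below the spread of the scaled target (~0.19 here)
  ens <- train_ensemble(ts$features, ts$labels, n_members = 4, epsilon = 0.01,
                        target = "updrs_normalized", updrs = updrs, seed = 2L)
  expect_identical(ens$training_meta$target, "updrs_normalized")
  expect_error(train_ensemble(ts$features, ts$labels, n_members = 4,
                              target = "updrs_normalized"),
               "requires updrs")
})
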