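# Shared fixture builders. Everything is generated in code; no stored data.

# a subject_log with given press times, constant 0.1 s holds unless given
make_log <- function(press, hold = 0.1, category = "LEFT",
                     subject_id = "S01", setting = "CLINIC", ...) {
  n <- length(press)
  subject_log(subject_id, setting,
              data.frame(press_time = press,
                         release_time = press + rep_len(hold, n),
                         key_category = rep_len(category, n),
                         stringsAsFactors = FALSE),
              ...)
}

# random well-formed log (sorted presses, non-negative holds)
random_log <- function(n, seed, setting = "CLINIC", subject_id = "R01",
                       special_frac = 0.2, span = n) {
  withr::with_seed(seed, {
    press <- sort(runif(n, 0, span))
    make_log(press,
             hold = runif(n, 0.02, 0.4),
             category = sample(c("LEFT", "RIGHT", "SPECIAL"), n, TRUE,
                               prob = c((1 - special_frac) / 2,
                                        (1 - special_frac) / 2, special_frac)),
             subject_id = subject_id, setting = setting)
  })
}

# hold-time series straight from vectors
make_series <- function(times, values = rep(0.1, length(times))) {
  structure(list(times = times, values = values), class = "ht_series")
}

# typing window from raw hold values
make_window <- function(ht, start = 0, len = 90) {
  structure(list(window_start = start, window_length = len,
                 ht_values = ht, keystroke_count = length(ht)),
            class = "typing_window")
}

# a small trained ensemble on strongly separated synthetic features
tiny_training_set <- function(n_pd = 4, n_ct = 4, windows = 6, seed = 99) {
  withr::with_seed(seed, {
    ids <- c(sprintf("P%d", seq_len(n_pd)), sprintf("C%d", seq_len(n_ct)))
    labels <- stats::setNames(rep(c(1, 0), c(n_pd, n_ct)), ids)
    feats <- lapply(labels, function(lab) {
      base <- if (lab == 1) 0.06 else 0.03
      m <- cbind(ht_mean = rnorm(windows, 0.1, 0.005),
                 ht_sd = rnorm(windows, base, 0.005),
                 ht_cv = rnorm(windows, base / 0.1, 0.05),
                 ht_iqr = rnorm(windows, base, 0.005),
                 ht_masd = rnorm(windows, base, 0.005),
                 ht_heavy_frac = pmax(0, rnorm(windows, base, 0.01)),
                 ht_capped_sd = rnorm(windows, base, 0.005))
      m
    })
    list(features = feats, labels = labels)
  })
}
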