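#' @keywords internal
"_PACKAGE"

# Deterministic derivation of stage/subject sub-seeds from a single master
# seed. Arithmetic stays below 2^53 so the modular reduction is exact in
# doubles; results fit in a 32-bit signed integer as set.seed() requires.
sub_seed <- function(seed, ...) {
  ks <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + k + 12345) %% 2147483647
    h <- (h * 69069 + 1) %% 2147483647
  }
  as.integer(h)
}

# run expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nqi <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_nqi <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
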