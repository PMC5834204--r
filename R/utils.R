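# Internal helpers: seed derivation, RNG hygiene, z-scoring, trailing slopes.

# Modular arithmetic on 31-bit integers using exact double arithmetic.
# a < 2^31, b < 2^31; split b so every intermediate stays below 2^53.
mulmod31 <- function(a, b, m = 2147483647) {
  b1 <- b %/% 65536
  b0 <- b %% 65536
  (((a * b1) %% m) * 65536 + a * b0) %% m
}

#' Derive a reproducible sub-seed
#'
#' Counter-based seed derivation: mixes a top-level seed with one or more
#' integer counters (e.g. day and throw number) so that every simulated
#' throw gets its own RNG stream while the whole cohort stays reproducible
#' from a single seed.
#'
#' @param seed Top-level integer seed.
#' @param ... Integer counters (day, throw, ...), mixed in order.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- abs(as.numeric(seed)) %% m
  for (k in c(...)) {
    s <- mulmod31(s + 1, 48271, m)
    s <- (s + (abs(as.numeric(k)) %% m)) %% m
    s <- mulmod31(s + 1, 69621, m)
  }
  as.integer(s %% (m - 2) + 1)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# z-score a vector; degenerate (zero variance) input is an error where the
# caller says so, otherwise returns zeros.
zscore <- function(x, allow_degenerate = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_degenerate) return(rep(0, length(x)))
    stop("cannot z-score a variable with zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Angular velocity from the trailing 20-sample linear fit
#'
#' Ordinary least-squares slope of angle against time over the `window`
#' samples strictly before `at_index`, the estimator used for the release
#' velocity of recorded lever trajectories.
#'
#' @param angles Numeric vector of lever angles (degrees) sampled uniformly.
#' @param at_index Sample index (1-based); the fit uses samples
#'   `at_index - window` to `at_index - 1`.
#' @param sample_rate Sampling rate in Hz.
#' @param window Number of trailing samples in the fit (default 20).
#' @return Angular velocity in degrees/s.
#' @export
estimate_angular_velocity <- function(angles, at_index, sample_rate = 1000,
                                      window = 20L) {
  if (at_index - window < 1L)
    stop("insufficient history: need ", window,
         " samples before index ", at_index, call. = FALSE)
  idx <- (at_index - window):(at_index - 1L)
  y <- angles[idx]
  t <- (idx - 1) / sample_rate
  tc <- t - mean(t)
  sum(tc * y) / sum(tc^2)
}

# Trailing OLS slope at every sample of a uniformly sampled angle series,
# as a linear filter (the abscissa is uniform so the weights are fixed).
# Samples with fewer than `window` predecessors inherit the first defined
# value, so downstream error trajectories have no gaps.
trailing_slope <- function(angles, sample_rate, window = 20L) {
  n <- length(angles)
  if (n < window + 1L)
    stop("trajectory too short for the ", window,
         "-sample velocity estimator", call. = FALSE)
  j <- seq_len(window)
  w <- (j - mean(j)) / sum((j - mean(j))^2) * sample_rate
  # out[i] = sum_j w_j * angles[i - window + j - 1]: a one-sided linear
  # filter with a zero weight at lag 0 (the fit excludes the sample itself)
  f <- c(0, rev(w))
  out <- as.numeric(stats::filter(angles, f, method = "convolution",
                                  sides = 1))
  out[seq_len(window)] <- out[window + 1L]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
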