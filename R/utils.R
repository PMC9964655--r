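#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows through explicitly passed integer
#' seeds; per-subject and per-trial seeds are derived from the master seed
#' by a fixed integer mixing scheme so that cohort runs are bit-reproducible
#' and individual trials can be regenerated in isolation.
#'
#' @param seed master seed (integer).
#' @param ... further integer components (subject id, stage index, ...).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 12345) %% m
  }
  as.integer(s)
}

#' Sample timestamps for a uniformly sampled series
#'
#' Sample indexing is 0-based with the time origin at the first sample,
#' so timestamps are `t = k / rate` seconds.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @return Numeric vector of length `n`.
#' @export
emg_times <- function(n, rate) {
  (seq_len(n) - 1) / rate
}

# internal: stop with a consistent message prefix
abort_emg <- function(...) stop(..., call. = FALSE)
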