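# Shared fixtures and independent oracles used across test files.

# A quiet subject profile with no amplitude jitter / interference / drift,
# for tests that need analytically clean signals.
clean_signal_params <- function(...) {
  signal_params(amp_jitter_sd = 0, interference_amp = 0, drift_amp = 0, ...)
}

# Brute-force reference classifier: literal truth-table evaluation of the
# three-state boolean logic, one (A, B, C) combination at a time.
oracle_classify <- function(ed, fds, eps, mu) {
  a <- ed > eps; b <- fds > mu; cc <- ed > fds
  out <- c(rest = (!a) && (!b),
           open = a && ((!b) || cc),
           close = b && ((!a) || (!cc)))
  stopifnot(sum(out) == 1)
  c(rest = 0L, open = -1L, close = 1L)[[names(which(out))]]
}

# O(N^2) double-loop cross-correlation, straight from the definition.
oracle_xcorr <- function(x, y, lags) {
  n <- length(x)
  sapply(lags, function(h) {
    s <- 0
    for (k in 0:(n - 1)) {
      xi <- k + h
      if (xi >= 0 && xi <= n - 1) s <- s + x[xi + 1] * y[k + 1]
    }
    s
  })
}

# Sequential (Type I) sums of squares by explicit design-matrix
# projections: project y onto the column space of the growing dummy-coded
# design and take the increments in explained sum of squares.
oracle_sequential_ss <- function(df) {
  n <- nrow(df)
  dummies <- function(f) {
    f <- factor(f)
    sapply(levels(f)[-1], function(l) as.numeric(f == l))
  }
  y <- df$d_l2
  blocks <- list(intercept = matrix(1, n, 1),
                 test = dummies(df$test),
                 order = dummies(df$order),
                 individual = dummies(df$individual))
  proj_ss <- function(X) {
    # explained SS of y under OLS on X, via the normal equations
    beta <- solve(crossprod(X), crossprod(X, y))
    fitted <- X %*% beta
    sum(fitted^2)
  }
  X <- NULL
  ss_prev <- 0
  out <- numeric(0)
  for (nm in names(blocks)) {
    X <- cbind(X, blocks[[nm]])
    ss <- proj_ss(X)
    out[nm] <- ss - ss_prev
    ss_prev <- ss
  }
  resid_ss <- sum(y^2) - ss_prev
  c(out[-1], residuals = resid_ss)
}

# Random balanced results table with arbitrary effects, for oracle checks.
# Order randomizations that exactly confound order with test are redrawn
# (the fitter rejects those by design).
random_results_table <- function(n_subjects, seed) {
  withr::with_seed(seed, {
    repeat {
      rows <- lapply(seq_len(n_subjects), function(s) {
        data.frame(subject_id = s, test = c("A", "B", "C", "D"),
                   order = sample(4), d_l2 = abs(rnorm(4, 3, 1)))
      })
      tab <- do.call(rbind, rows)
      X <- stats::model.matrix(~ factor(test) + factor(order) +
                                 factor(subject_id), data = tab)
      if (qr(X)$rank == ncol(X)) return(tab)
    }
  })
}

# Amplitude of the f Hz component of x (discrete Fourier projection on
# the steady-state portion), for spectral checks.
tone_amplitude <- function(x, f, fs, skip_s = 2) {
  i0 <- as.integer(skip_s * fs) + 1L
  x <- x[i0:length(x)]
  t <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * cos(2 * pi * f * t))^2 + mean(x * sin(2 * pi * f * t))^2)
}
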