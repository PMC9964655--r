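test_that("exactly one gesture is true for every boolean combination", {
  # exhaustive enumeration of the three boolean outputs over all 8
  # combinations of (A, B, C)
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE))
    for (cc in c(FALSE, TRUE)) {
      rest <- (!a) && (!b)
      open <- a && ((!b) || cc)
      close <- b && ((!a) || (!cc))
      expect_equal(rest + open + close, 1,
                   label = sprintf("A=%d B=%d C=%d", a, b, cc))
    }
  # and every numerically realizable combination matches the brute-force
  # truth-table oracle (with unequal thresholds all 8 are realizable)
  eps <- 0.15; mu <- 0.45
  cases <- expand.grid(ed = c(0, 0.1, 0.2, 0.3, 0.6),
                       fds = c(0, 0.2, 0.3, 0.5, 0.9))
  combos <- unique(data.frame(a = cases$ed > eps, b = cases$fds > mu,
                              cc = cases$ed > cases$fds))
  expect_gte(nrow(combos), 7) # only A&C impossible-at-once combos missing
  for (i in seq_len(nrow(cases)))
    expect_equal(classify_sample(cases$ed[i], cases$fds[i], eps, mu),
                 oracle_classify(cases$ed[i], cases$fds[i], eps, mu))
})

test_that("worked threshold-logic cases classify as expected", {
  # both below thresholds -> rest
  expect_equal(classify_sample(0.05, 0.05, 0.15, 0.15), 0)
  # only extensor active -> open
  expect_equal(classify_sample(0.5, 0.05, 0.15, 0.15), -1)
  # only flexor active -> close
  expect_equal(classify_sample(0.05, 0.5, 0.15, 0.15), 1)
  # both active: dominance decides
  expect_equal(classify_sample(0.5, 0.4, 0.15, 0.15), -1)
  expect_equal(classify_sample(0.4, 0.5, 0.15, 0.15), 1)
  # exact tie with both active: strict C yields close
  expect_equal(classify_sample(0.5, 0.5, 0.15, 0.15), 1)
  # equality with a threshold counts as NOT exceeding
  expect_equal(classify_sample(0.15, 0.05, 0.15, 0.15), 0)
  expect_error(classify_sample(NaN, 0.1, 0.15, 0.15), "finite")
  expect_error(classify_sample(0.1, 0.1, 0, 0.15), "positive")
})

test_that("a grid of nEMG pairs matches the brute-force classifier", {
  grid <- seq(0, 1, by = 0.2)
  for (eps in c(0.1, 0.3)) for (mu in c(0.1, 0.25)) {
    for (ed in grid) for (fds in grid) {
      expect_equal(classify_sample(ed, fds, eps, mu),
                   oracle_classify(ed, fds, eps, mu),
                   label = sprintf("ed=%g fds=%g eps=%g mu=%g",
                                   ed, fds, eps, mu))
    }
  }
})

test_that("dominance and monotone stability hold when both muscles fire", {
  eps <- 0.15; mu <- 0.15
  withr::with_seed(10, {
    for (i in 1:200) {
      ed <- runif(1, eps + 1e-6, 1.2)
      fds <- runif(1, mu + 1e-6, 1.2)
      if (ed == fds) next
      expect_equal(classify_sample(ed, fds, eps, mu),
                   if (ed > fds) -1 else 1)
    }
  })
  # increasing nEMG_ED at fixed nEMG_FDS never jumps open -> close
  fds <- 0.4
  path <- classify_sample(seq(0, 1, by = 0.01), fds, eps, mu)
  jumps <- cbind(head(path, -1), tail(path, -1))
  expect_false(any(jumps[, 1] == -1 & jumps[, 2] == 1))
})

test_that("series classification is sample-wise with length preserved", {
  par <- list(epsilon = 0.15, mu = 0.15)
  nem <- structure(list(ed = rep(0, 40), fds = rep(0, 40),
                        sampling_rate = 20),
                   class = "normalized_emg")
  g <- classify_series(nem, par)
  expect_true(all(g$values == 0))
  expect_length(g$values, 40)
  # alternating blocks above threshold -> alternating open/close blocks
  nem2 <- structure(list(ed = rep(c(0.5, 0), each = 10, times = 2),
                         fds = rep(c(0, 0.5), each = 10, times = 2),
                         sampling_rate = 20),
                    class = "normalized_emg")
  g2 <- classify_series(nem2, par)
  expect_equal(g2$values, rep(c(-1L, 1L), each = 10, times = 2))
  nem3 <- structure(list(ed = rep(0, 5), fds = rep(0, 4),
                         sampling_rate = 20),
                    class = "normalized_emg")
  expect_error(classify_series(nem3, par), "length mismatch")
})

test_that("gesture series validate codes and round-trip through CSV", {
  expect_error(gesture_series(c(0, 2)), "values")
  g <- gesture_series(c(-1, 0, 1, 1), role = "recognized")
  path <- withr::local_tempfile(fileext = ".csv")
  write_gesture_csv(g, path)
  g2 <- read_gesture_csv(path)
  expect_identical(g2$values, g$values)
  # corrupt a code: row-level diagnostics
  df <- utils::read.csv(path)
  df$gesture[2] <- 7
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_gesture_csv(path), "rows 2")
})
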