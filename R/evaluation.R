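#' Raw cross-correlation of two coded series
#'
#' Sliding dot product with implicit zero padding:
#' \deqn{r_{xy}(h) = \sum_{n=0}^{N-h-1} x(n+h)\, y^*(n), \quad 0 \le h \le N-1}
#' and \eqn{r_{xy}(-h) = r^*_{yx}(h)} for negative lags (inputs here are
#' real, so conjugation is the identity). No demeaning or normalization is
#' applied.
#'
#' @param x,y equal-length finite numeric series.
#' @param lags integer lags at which to evaluate (default all,
#'   `-(N-1):(N-1)`).
#' @return A `data.frame` with columns `lag` and `r`.
#' @export
cross_correlate <- function(x, y, lags = NULL) {
  if (length(x) == 0L || length(y) == 0L)
    abort_emg("cross_correlate: empty series")
  if (length(x) != length(y))
    abort_emg("cross_correlate: series must have equal length")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    abort_emg("cross_correlate: series must be finite")
  n <- length(x)
  if (is.null(lags)) lags <- -(n - 1):(n - 1)
  if (any(abs(lags) > n - 1))
    abort_emg("cross_correlate: |lag| must be < series length")
  r <- vapply(lags, function(h) {
    if (h >= 0) sum(x[(h + 1):n] * y[1:(n - h)])
    else sum(y[(-h + 1):n] * x[1:(n + h)]) # r_yx(-h)
  }, numeric(1))
  data.frame(lag = as.integer(lags), r = r)
}

#' Synchronize target and recognized gesture series
#'
#' Recognition lags the target (user response time plus the processing
#' chain), so the delay time `T_d` is the non-negative lag, up to
#' `max_lag_s`, at which the cross-correlation of the two sequences is
#' highest (ties broken toward the smallest lag). The recognized series is
#' shifted back by that lag and the target is cut off at the end to make
#' both equal in length. A flat correlation (all-constant series) falls
#' back to `T_d = 0` with a warning. `T_d` is a single constant per test.
#'
#' @param target a [gesture_series()] (role `"target"`).
#' @param recognized a [gesture_series()] (role `"recognized"`).
#' @param max_lag_s largest delay searched, seconds (default 2).
#' @return An object of class `sync_result`: `delay_samples`,
#'   `delay_seconds`, `aligned_target`, `aligned_recognized`, `t_s`.
#' @export
synchronize <- function(target, recognized, max_lag_s = 2.0) {
  stopifnot(inherits(target, "gesture_series"),
            inherits(recognized, "gesture_series"))
  if (target$sampling_rate != recognized$sampling_rate)
    abort_emg("synchronize: sampling rates differ")
  if (length(target$values) != length(recognized$values))
    abort_emg("synchronize: series must have equal nominal length")
  rate <- target$sampling_rate
  n <- length(target$values)
  max_lag <- min(n - 1L, as.integer(floor(max_lag_s * rate)))
  cc <- cross_correlate(recognized$values, target$values, lags = 0:max_lag)
  if (nrow(cc) > 1 && diff(range(cc$r)) == 0) {
    warning("synchronize: flat cross-correlation (constant series); ",
            "falling back to T_d = 0", call. = FALSE)
    h <- 0L
  } else {
    h <- cc$lag[which.max(cc$r)] # which.max takes the first maximum
  }
  keep <- n - h
  structure(list(
    delay_samples = h,
    delay_seconds = h / rate,
    aligned_target = gesture_series(target$values[seq_len(keep)],
                                    sampling_rate = rate, role = "target"),
    aligned_recognized = gesture_series(
      recognized$values[(h + 1):n], sampling_rate = rate,
      role = "recognized"),
    t_s = 1 / rate),
    class = "sync_result")
}

#' L2 performance score of a synchronized trial
#'
#' Squared Euclidean distance between the aligned coded series, scaled by
#' the sampling period:
#' \deqn{d_{L2}(x, x^*) = \sum_i (x^*_i - x_i)^2 \, T_s}
#' With the coding open = -1, rest = 0, close = +1, an open/close confusion
#' costs four times an open-or-close/rest confusion per sample — the
#' quadratic cost penalizes the dangerous error type. Lower is better;
#' 0 means the aligned series are identical.
#'
#' @param sync a `sync_result` from [synchronize()].
#' @return An object of class `performance_score`: `d_l2`, `n_samples`,
#'   `t_s`.
#' @export
l2_distance <- function(sync) {
  stopifnot(inherits(sync, "sync_result"))
  x_star <- sync$aligned_target$values
  x <- sync$aligned_recognized$values
  if (length(x_star) != length(x))
    abort_emg("l2_distance: aligned series length mismatch")
  structure(list(d_l2 = sum((x_star - x)^2) * sync$t_s,
                 n_samples = length(x), t_s = sync$t_s),
            class = "performance_score")
}

#' Score one trial end to end
#'
#' Convenience wrapper: synchronize then score.
#'
#' @inheritParams synchronize
#' @return List with `t_d_seconds`, `delay_samples`, `d_l2`, `n_samples`.
#' @export
evaluate_trial <- function(target, recognized, max_lag_s = 2.0) {
  sync <- synchronize(target, recognized, max_lag_s)
  sc <- l2_distance(sync)
  list(t_d_seconds = sync$delay_seconds,
       delay_samples = sync$delay_samples,
       d_l2 = sc$d_l2, n_samples = sc$n_samples)
}
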