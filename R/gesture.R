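#' Gesture codes
#'
#' Discrete gesture states coded so that the distance between open and
#' close is twice the distance between either and rest:
#' Open = -1, Rest = 0, Close = +1.
#'
#' @format Named integer vector.
#' @export
GESTURES <- c(open = -1L, rest = 0L, close = 1L)

#' Discrete-event gesture series at 20 Hz
#'
#' @param values integer vector over \{-1, 0, +1\}.
#' @param sampling_rate Hz (default 20).
#' @param role `"target"` or `"recognized"`.
#' @return An object of class `gesture_series`.
#' @export
gesture_series <- function(values, sampling_rate = 20,
                           role = c("target", "recognized")) {
  role <- match.arg(role)
  if (length(values) == 0L)
    abort_emg("gesture_series: empty series")
  if (anyNA(values) || !all(values %in% c(-1, 0, 1)))
    abort_emg("gesture_series: values must all be in {-1, 0, +1}")
  structure(list(values = as.integer(values),
                 sampling_rate = sampling_rate, role = role),
            class = "gesture_series")
}

#' @export
print.gesture_series <- function(x, ...) {
  cat(sprintf("<gesture_series: %s, %d samples @ %g Hz (%.1f s)>\n",
              x$role, length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate))
  invisible(x)
}

#' Three-state threshold gesture classifier (single sample)
#'
#' Boolean threshold logic on the normalized EMG pair. With
#' `A = nemg_ed > epsilon`, `B = nemg_fds > mu` and
#' `C = nemg_ed > nemg_fds` (all strict inequalities):
#' \deqn{REST = \bar A \cdot \bar B,\quad
#'       OPEN = A \cdot (\bar B + C),\quad
#'       CLOSE = B \cdot (\bar A + \bar C)}
#' For every combination of (A, B, C) exactly one output is true. When
#' both muscles exceed their thresholds the gesture follows the larger
#' nEMG; an exact tie (C false by strictness) yields CLOSE.
#'
#' @param nemg_ed,nemg_fds normalized EMG values (MVC units); vectorized.
#' @param epsilon,mu deactivation thresholds (> 0).
#' @return Integer code(s): -1 open, 0 rest, +1 close.
#' @export
classify_sample <- function(nemg_ed, nemg_fds, epsilon, mu) {
  if (anyNA(nemg_ed) || anyNA(nemg_fds) ||
      !all(is.finite(nemg_ed)) || !all(is.finite(nemg_fds)))
    abort_emg("classify_sample: nEMG inputs must be finite (no NaN)")
  if (!is.finite(epsilon) || !is.finite(mu) || epsilon <= 0 || mu <= 0)
    abort_emg("classify_sample: thresholds must be positive and finite")
  a <- nemg_ed > epsilon
  b <- nemg_fds > mu
  cc <- nemg_ed > nemg_fds
  open <- a & (!b | cc)
  close <- b & (!a | !cc)
  ifelse(open, GESTURES[["open"]],
         ifelse(close, GESTURES[["close"]], GESTURES[["rest"]]))
}

#' Classify a whole normalized EMG series
#'
#' Sample-wise application of [classify_sample()]; no smoothing, hysteresis
#' or minimum-dwell debouncing.
#'
#' @param nemg a `normalized_emg` at 20 Hz.
#' @param params a [calibration_params()] supplying `epsilon` and `mu`.
#' @return A [gesture_series()] with `role = "recognized"` and the same
#'   length as the input.
#' @export
classify_series <- function(nemg, params) {
  if (length(nemg$ed) != length(nemg$fds))
    abort_emg("classify_series: channel length mismatch")
  gesture_series(classify_sample(nemg$ed, nemg$fds,
                                 params$epsilon, params$mu),
                 sampling_rate = nemg$sampling_rate, role = "recognized")
}

#' Expand a target gesture sequence into a 20 Hz series
#'
#' @param target a [target_sequence()].
#' @param rate output sampling rate (default 20 Hz).
#' @return A [gesture_series()] with `role = "target"`.
#' @export
target_series <- function(target, rate = 20) {
  per <- target$gesture_duration * rate
  if (abs(per - round(per)) > 1e-9)
    abort_emg("target_series: gesture duration not a whole number of ",
              "samples at ", rate, " Hz")
  gesture_series(rep(target$gestures, each = as.integer(round(per))),
                 sampling_rate = rate, role = "target")
}

#' Write / read a gesture series as CSV
#'
#' Columns `t_sec`, `gesture` (integer -1/0/+1); the same dialect is used
#' for target and recognized series so downstream scoring is
#' source-agnostic.
#'
#' @param series a [gesture_series()].
#' @param path file path.
#' @export
write_gesture_csv <- function(series, path) {
  df <- data.frame(t_sec = emg_times(length(series$values),
                                     series$sampling_rate),
                   gesture = series$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gesture_csv
#' @param role role to assign on read.
#' @export
read_gesture_csv <- function(path, role = "recognized") {
  df <- utils::read.csv(path)
  if (!all(c("t_sec", "gesture") %in% names(df)))
    abort_emg("read_gesture_csv: expected columns t_sec, gesture in ", path)
  bad <- which(!df$gesture %in% c(-1, 0, 1))
  if (length(bad))
    abort_emg("read_gesture_csv: invalid gesture codes in ", path,
              " at rows ", paste(utils::head(bad, 5), collapse = ", "))
  rate <- if (nrow(df) > 1) 1 / mean(diff(df$t_sec)) else 20
  gesture_series(df$gesture, sampling_rate = round(rate, 6), role = role)
}
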