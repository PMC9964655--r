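#' Design a second-order IIR notch filter
#'
#' Constrained-poles biquad notch (constrained to place a zero pair on the
#' unit circle at the notch frequency), quality factor `q`. Applied
#' causally; used to suppress 50 Hz mains interference.
#'
#' @param freq notch frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param q quality factor (default 30).
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
design_notch <- function(freq, fs, q = 30) {
  stopifnot(freq > 0, freq < fs / 2, q > 0)
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch and high-pass filter a raw recording
#'
#' Conditioning front end: per channel, a causal 50 Hz notch (Q = 30)
#' followed by a causal 2nd-order Butterworth high-pass at 10 Hz, isolating
#' the spectral content of interest and rejecting baseline drift. Filters
#' are applied forward only: the original algorithm runs sample-by-sample
#' on a real-time microcontroller, so zero-phase filtering would
#' misrepresent its latency.
#'
#' @param recording a [raw_recording()] at 200 Hz, at least 1 s long.
#' @param notch_hz notch frequency (default 50).
#' @param highpass_hz high-pass cutoff (default 10).
#' @return A list of class `filtered_emg` with elements `ed`, `fds`,
#'   `sampling_rate`; length preserved.
#' @export
filter_raw <- function(recording, notch_hz = 50, highpass_hz = 10) {
  if (!inherits(recording, "raw_recording"))
    abort_emg("filter_raw: input must be a raw_recording")
  fs <- recording$sampling_rate
  n <- length(recording$ed)
  if (n < fs)
    abort_emg("filter_raw: recording shorter than the 1 s filter warm-up")
  nf <- design_notch(notch_hz, fs)
  hp <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
  one <- function(x) {
    y <- signal::filter(signal::Arma(b = nf$b, a = nf$a), x)
    as.numeric(signal::filter(hp, y))
  }
  structure(list(ed = one(recording$ed), fds = one(recording$fds),
                 sampling_rate = fs),
            class = "filtered_emg")
}

#' RMS rectification, smoothing and decimation to 20 Hz
#'
#' Rectifies the filtered signals by a trailing (causal) root-mean-square
#' over a 50 ms window (10 samples at 200 Hz; shortened windows at the
#' start), smooths with a causal 2nd-order Butterworth low-pass at 2 Hz,
#' and keeps every 10th sample, yielding the 20 Hz rectified EMG (rEMG)
#' series. Output timestamps are `t = k/20` s, `k` 0-based. The 2 Hz
#' low-pass already limits bandwidth well below the 10 Hz output Nyquist,
#' so no additional anti-alias filter is applied. Values are clamped at 0
#' (the low-pass can undershoot slightly on sharp onsets).
#'
#' @param filtered a `filtered_emg` (or `raw_recording`) at 200 Hz.
#' @param window_ms RMS window length in milliseconds (default 50).
#' @param lowpass_hz smoothing cutoff in Hz (default 2).
#' @param decim decimation factor (default 10).
#' @return A list of class `rectified_emg` with non-negative `ed`, `fds`
#'   and `sampling_rate = 200/decim = 20` Hz.
#' @export
rectify_rms <- function(filtered, window_ms = 50, lowpass_hz = 2,
                        decim = 10) {
  if (!all(c("ed", "fds", "sampling_rate") %in% names(filtered)))
    abort_emg("rectify_rms: input must carry ed, fds and sampling_rate")
  fs <- filtered$sampling_rate
  w <- window_ms * fs / 1000
  if (abs(w - round(w)) > 1e-8)
    abort_emg("rectify_rms: window must convert to an integer number of ",
              "samples (got ", w, ")")
  w <- as.integer(round(w))
  if (w < 1L) abort_emg("rectify_rms: window shorter than 1 sample")
  lp <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  one <- function(x) {
    n <- length(x)
    cs <- cumsum(x^2)
    lead <- c(rep(0, w), cs[seq_len(n - w)])
    len <- pmin(seq_len(n), w)           # shortened windows at the start
    rms <- sqrt((cs - lead) / len)
    sm <- as.numeric(signal::filter(lp, rms))
    pmax(sm[seq(1L, n, by = decim)], 0)
  }
  structure(list(ed = one(filtered$ed), fds = one(filtered$fds),
                 sampling_rate = fs / decim),
            class = "rectified_emg")
}

#' Normalize rectified EMG to MVC units
#'
#' Divides each rEMG channel by the subject's maximal voluntary contraction
#' (MVC) for that muscle, obtained in a prior calibration, so that 1
#' corresponds to the calibration maximum. Values are deliberately not
#' clipped at 1: trial contractions can exceed the calibration MVC, and the
#' deactivation thresholds are defined relative to rest-phase minima, so
#' clipping would only destroy information.
#'
#' @param rectified a `rectified_emg` at 20 Hz.
#' @param params a [calibration_params()] (only `mvc_ed`, `mvc_fds` used).
#' @return A list of class `normalized_emg` with `ed`, `fds` in MVC units
#'   and `sampling_rate`.
#' @export
normalize_emg <- function(rectified, params) {
  if (!all(c("ed", "fds") %in% names(rectified)))
    abort_emg("normalize_emg: input must carry ed and fds channels")
  if (is.null(params$mvc_ed) || is.null(params$mvc_fds) ||
      !is.finite(params$mvc_ed) || !is.finite(params$mvc_fds) ||
      params$mvc_ed <= 0 || params$mvc_fds <= 0)
    abort_emg("normalize_emg: calibration failure - MVC values must be ",
              "finite and strictly positive")
  structure(list(ed = rectified$ed / params$mvc_ed,
                 fds = rectified$fds / params$mvc_fds,
                 sampling_rate = rectified$sampling_rate),
            class = "normalized_emg")
}

#' Write a processed 20 Hz series as CSV
#'
#' Columns `t_sec`, `nemg_ed`, `nemg_fds`.
#'
#' @param nemg a `normalized_emg`.
#' @param path file path.
#' @export
write_nemg_csv <- function(nemg, path) {
  df <- data.frame(t_sec = emg_times(length(nemg$ed), nemg$sampling_rate),
                   nemg_ed = nemg$ed, nemg_fds = nemg$fds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
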