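#' Two-channel raw surface EMG recording
#'
#' Container for a raw two-channel (extensor digitorum ED, flexor digitorum
#' FDS) surface EMG recording sampled at 200 Hz. Both channels must have
#' equal length; the sample count must equal `round(duration * rate)`.
#'
#' @param ed,fds numeric vectors of raw samples (millivolts).
#' @param sampling_rate sampling rate in Hz (default 200).
#' @param kind `"trial"` or `"calibration"`.
#' @return An object of class `raw_recording`: a list with elements `ed`,
#'   `fds`, `sampling_rate`, `duration` (seconds) and `kind`.
#' @export
raw_recording <- function(ed, fds, sampling_rate = 200,
                          kind = c("trial", "calibration")) {
  kind <- match.arg(kind)
  if (length(ed) == 0L || length(fds) == 0L)
    abort_emg("raw_recording: channels must be non-empty")
  if (length(ed) != length(fds))
    abort_emg("raw_recording: ED and FDS channels must have equal length (",
              length(ed), " vs ", length(fds), ")")
  if (anyNA(ed) || anyNA(fds))
    abort_emg("raw_recording: channels must not contain NA/NaN")
  structure(
    list(ed = as.numeric(ed), fds = as.numeric(fds),
         sampling_rate = sampling_rate,
         duration = length(ed) / sampling_rate,
         kind = kind),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording: %s, %.1f s @ %g Hz, %d samples/channel>\n",
              x$kind, x$duration, x$sampling_rate, length(x$ed)))
  invisible(x)
}

#' Write / read a raw recording as CSV
#'
#' Plain-text interchange format: columns `t_sec`, `emg_ed_mv`,
#' `emg_fds_mv`, header row mandatory.
#'
#' @param rec a [raw_recording()].
#' @param path file path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns a [raw_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  df <- data.frame(t_sec = emg_times(length(rec$ed), rec$sampling_rate),
                   emg_ed_mv = rec$ed, emg_fds_mv = rec$fds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate,kind metadata not carried by the CSV itself.
#' @export
read_recording_csv <- function(path, sampling_rate = 200, kind = "trial") {
  df <- utils::read.csv(path)
  need <- c("t_sec", "emg_ed_mv", "emg_fds_mv")
  if (!all(need %in% names(df)))
    abort_emg("read_recording_csv: expected columns ",
              paste(need, collapse = ", "))
  raw_recording(df$emg_ed_mv, df$emg_fds_mv,
                sampling_rate = sampling_rate, kind = kind)
}
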