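#' Calibration parameters
#'
#' Bundle of per-subject calibration outputs: MVC amplitudes for the two
#' muscles and the muscular deactivation thresholds epsilon (ED) and mu
#' (FDS), in MVC units.
#'
#' @param mvc_ed,mvc_fds maximal voluntary contraction amplitudes (mV, > 0).
#' @param epsilon,mu deactivation thresholds (MVC units, >= 0.1 by
#'   construction: rest-phase minimum plus 0.1).
#' @param phase_bounds optional 3 x 2 matrix of the calibration phase
#'   intervals (seconds): rest, maximal flexion, maximal extension.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(mvc_ed, mvc_fds, epsilon, mu,
                               phase_bounds = default_phase_bounds()) {
  if (mvc_ed <= 0 || mvc_fds <= 0)
    abort_emg("calibration_params: MVC values must be strictly positive")
  if (epsilon < 0.1 || mu < 0.1)
    abort_emg("calibration_params: thresholds below the 0.1 floor")
  structure(list(mvc_ed = mvc_ed, mvc_fds = mvc_fds,
                 epsilon = epsilon, mu = mu,
                 phase_bounds = phase_bounds),
            class = "calibration_params")
}

#' @rdname calibration_params
#' @export
default_phase_bounds <- function() {
  matrix(c(0, 8, 8, 16, 16, 24), ncol = 2, byrow = TRUE,
         dimnames = list(c("rest", "flexion", "extension"), c("from", "to")))
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(paste0("<calibration_params: MVC_ED = %.3f mV, ",
                     "MVC_FDS = %.3f mV, epsilon = %.3f, mu = %.3f>\n"),
              x$mvc_ed, x$mvc_fds, x$epsilon, x$mu))
  invisible(x)
}

#' Maximal voluntary contraction from a calibration recording
#'
#' The MVC of each muscle is the maximum of its rectified EMG (rEMG) over
#' the whole 24 s calibration.
#'
#' @param calib_rectified a `rectified_emg` computed from a calibration
#'   recording (24 s, i.e. 480 samples at 20 Hz).
#' @return Named list `mvc_ed`, `mvc_fds`.
#' @export
compute_mvc <- function(calib_rectified) {
  if (!inherits(calib_rectified, "rectified_emg"))
    abort_emg("compute_mvc: input must be a rectified_emg")
  mvc_ed <- max(calib_rectified$ed)
  mvc_fds <- max(calib_rectified$fds)
  if (mvc_ed <= 0 || mvc_fds <= 0)
    abort_emg("compute_mvc: calibration failure - flat channel ",
              "(maximum rEMG is 0)")
  list(mvc_ed = mvc_ed, mvc_fds = mvc_fds)
}

#' Muscular deactivation thresholds from the relaxation phase
#'
#' epsilon (ED) and mu (FDS) are the minima of the normalized EMG over the
#' relaxation phase of the calibration, plus a constant of 0.1. The
#' relaxation phase is taken as the nominal first 8 s window (no onset
#' detection).
#'
#' @param calib_normalized a `normalized_emg` from the calibration.
#' @param rest_phase numeric length-2 interval in seconds (default
#'   `c(0, 8)`).
#' @return Named list `epsilon`, `mu`.
#' @export
compute_thresholds <- function(calib_normalized, rest_phase = c(0, 8)) {
  if (!all(c("ed", "fds", "sampling_rate") %in% names(calib_normalized)))
    abort_emg("compute_thresholds: input must carry ed, fds, sampling_rate")
  t <- emg_times(length(calib_normalized$ed), calib_normalized$sampling_rate)
  idx <- which(t >= rest_phase[1] & t < rest_phase[2])
  if (length(idx) == 0L)
    abort_emg("compute_thresholds: empty rest window")
  eps <- min(calib_normalized$ed[idx]) + 0.1
  mu <- min(calib_normalized$fds[idx]) + 0.1
  if (eps >= 1 || mu >= 1)
    warning("compute_thresholds: noisy rest phase - a deactivation ",
            "threshold is >= 1 MVC; calibration quality is suspect",
            call. = FALSE)
  list(epsilon = eps, mu = mu)
}

#' Full calibration from a raw 24 s recording
#'
#' Runs the conditioning chain on the calibration recording, extracts MVC
#' values from the rEMG and deactivation thresholds from the rest-phase
#' nEMG.
#'
#' @param recording a [raw_recording()] with `kind = "calibration"`,
#'   duration 24 s.
#' @return A [calibration_params()].
#' @export
calibrate <- function(recording) {
  if (!inherits(recording, "raw_recording") ||
      recording$kind != "calibration")
    abort_emg("calibrate: input must be a raw_recording of kind ",
              "'calibration'")
  if (abs(recording$duration - 24) > 1e-9)
    abort_emg("calibrate: calibration recordings last 24 s (got ",
              recording$duration, " s)")
  rect <- rectify_rms(filter_raw(recording))
  mvc <- compute_mvc(rect)
  nemg <- normalize_emg(rect, mvc)
  thr <- compute_thresholds(nemg, rest_phase = default_phase_bounds()[1, ])
  calibration_params(mvc$mvc_ed, mvc$mvc_fds, thr$epsilon, thr$mu)
}

#' Serialize / read calibration parameters as JSON
#'
#' @param params a [calibration_params()].
#' @param path file path.
#' @export
write_calibration_json <- function(params, path) {
  jsonlite::write_json(
    list(mvc_ed = params$mvc_ed, mvc_fds = params$mvc_fds,
         epsilon = params$epsilon, mu = params$mu),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(x$mvc_ed, x$mvc_fds, x$epsilon, x$mu)
}
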