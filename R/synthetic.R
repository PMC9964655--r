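#' Signal-model parameters for the synthetic EMG generator
#'
#' Defaults define the simulated study conditions: an sEMG carrier modeled
#' as zero-mean Gaussian noise band-passed to 20-90 Hz (inside the 100 Hz
#' Nyquist limit of 200 Hz sampling), amplitude-modulated by trapezoidal
#' activation envelopes with 100 ms rise/fall; additive 50 Hz mains
#' interference at 10% of MVC and 0.5 Hz sinusoidal drift at 5% of MVC, so
#' the notch and high-pass stages are functionally necessary. Voluntary
#' trial contractions sit at 0.6 MVC; deliberately weak (sub-threshold)
#' activations at 0.05 MVC; per-gesture contraction amplitudes carry
#' lognormal jitter; injected error episodes last U(0.25, 0.75) s.
#'
#' @param contraction_level voluntary contraction amplitude (MVC fraction).
#' @param weak_level sub-threshold activation amplitude (MVC fraction).
#' @param amp_jitter_sd lognormal sd of per-gesture amplitude jitter.
#' @param ramp_s envelope rise/fall time (s).
#' @param carrier_band carrier band edges (Hz).
#' @param interference_amp 50 Hz interference amplitude (MVC fraction).
#' @param interference_hz mains frequency (Hz).
#' @param drift_amp drift amplitude (MVC fraction).
#' @param drift_hz drift frequency (Hz).
#' @param error_dur_range min/max duration of an injected error episode (s).
#' @param error_types error taxonomy to draw from (uniformly); restrict to
#'   a subset to study one failure mode in isolation.
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(contraction_level = 0.6, weak_level = 0.05,
                          amp_jitter_sd = 0.15, ramp_s = 0.1,
                          carrier_band = c(20, 90),
                          interference_amp = 0.10, interference_hz = 50,
                          drift_amp = 0.05, drift_hz = 0.5,
                          error_dur_range = c(0.25, 0.75),
                          error_types = c("wrong_muscle", "co_contraction",
                                          "weak")) {
  structure(as.list(environment()), class = "signal_params")
}

#' Synthetic subject profile
#'
#' Per-subject physiological parameters: MVC amplitudes, rest-phase muscle
#' tone (as a fraction of MVC, strictly below the 0.1 threshold floor so a
#' resting subject is always recognizable as REST), the response-delay
#' distribution (truncated normal) and a skill scalar in `[0, 1]` scaling
#' the subject's baseline error rate.
#'
#' @param subject_id integer id.
#' @param mvc_ed,mvc_fds MVC amplitudes (mV, > 0).
#' @param rest_level_ed,rest_level_fds rest tone (MVC fraction, in
#'   `[0, 0.1)`).
#' @param response_delay_mean,response_delay_sd seconds; delays are drawn
#'   from a normal truncated to `[0.05, 1.5]` s (degenerate `sd = 0` gives
#'   the clipped mean, and a zero mean with zero sd gives exactly 0 for
#'   idealized subjects).
#' @param skill scalar in `[0, 1]`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, mvc_ed = 2, mvc_fds = 2,
                            rest_level_ed = 0.03, rest_level_fds = 0.03,
                            response_delay_mean = 0.4,
                            response_delay_sd = 0.1, skill = 0.5) {
  if (mvc_ed <= 0 || mvc_fds <= 0)
    abort_emg("subject_profile: MVC amplitudes must be > 0")
  if (rest_level_ed < 0 || rest_level_ed >= 0.1 ||
      rest_level_fds < 0 || rest_level_fds >= 0.1)
    abort_emg("subject_profile: rest levels must lie in [0, 0.1) so rest ",
              "stays below the deactivation thresholds")
  if (response_delay_mean < 0 || response_delay_sd < 0)
    abort_emg("subject_profile: delay parameters must be non-negative")
  if (response_delay_mean > 2)
    abort_emg("subject_profile: mean response delay plus chain latency ",
              "must stay well below the 3 s gesture duration")
  if (skill < 0 || skill > 1)
    abort_emg("subject_profile: skill must lie in [0, 1]")
  structure(list(subject_id = as.integer(subject_id), mvc_ed = mvc_ed,
                 mvc_fds = mvc_fds, rest_level_ed = rest_level_ed,
                 rest_level_fds = rest_level_fds,
                 response_delay_mean = response_delay_mean,
                 response_delay_sd = response_delay_sd, skill = skill),
            class = "subject_profile")
}

#' Draw a cohort of random subject profiles
#'
#' MVCs U(1.5, 3) mV, rest tone U(0.01, 0.05) MVC, response-delay mean
#' U(0.30, 0.55) s with sd U(0.05, 0.12) s, skill U(0, 1) — a healthy young
#' cohort with heterogeneous ability, the main source of the strong
#' between-individual variance the blocking factor absorbs.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @return List of [subject_profile()]s.
#' @export
generate_subject_profiles <- function(n_subjects, seed) {
  withr::with_seed(derive_seed(seed, 101), {
    lapply(seq_len(n_subjects), function(i)
      subject_profile(
        subject_id = i,
        mvc_ed = stats::runif(1, 1.5, 3), mvc_fds = stats::runif(1, 1.5, 3),
        rest_level_ed = stats::runif(1, 0.01, 0.05),
        rest_level_fds = stats::runif(1, 0.01, 0.05),
        response_delay_mean = stats::runif(1, 0.30, 0.55),
        response_delay_sd = stats::runif(1, 0.05, 0.12),
        skill = stats::runif(1)))
  })
}

#' Feedback-condition effect
#'
#' Behavioral effect of one feedback condition: the per-gesture probability
#' of an incorrect/unstable activation and any extra response delay. The
#' four conditions cross kinesthetic feedback (exoskeleton movement; tests
#' A, B) with EMG-based visual biofeedback (tests A, C); test D has
#' neither.
#'
#' @param condition one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param error_prob probability per gesture of an injected error, in
#'   `[0, 1]`.
#' @param extra_delay seconds added to the response delay.
#' @return An object of class `condition_effect`.
#' @export
condition_effect <- function(condition, error_prob, extra_delay = 0) {
  if (!condition %in% c("A", "B", "C", "D"))
    abort_emg("condition_effect: condition must be one of A, B, C, D")
  if (error_prob < 0 || error_prob > 1)
    abort_emg("condition_effect: error_prob must lie in [0, 1]")
  structure(list(condition = condition, error_prob = error_prob,
                 extra_delay = extra_delay),
            class = "condition_effect")
}

#' Default condition effects
#'
#' Error probabilities ordered C < D < A ~ B: visual biofeedback alone
#' (test C) yields the fewest control errors, no feedback (D) is
#' intermediate, and the kinesthetic conditions (A, B) are worst because
#' the exoskeleton's lagging movement gives correction cues too late.
#' Magnitudes are set so mean L2 scores land in a plausible range for a
#' 1-min 20-gesture test (roughly 2.9-3.4).
#'
#' @return Named list of [condition_effect()]s.
#' @export
default_condition_effects <- function() {
  list(A = condition_effect("A", 0.062),
       B = condition_effect("B", 0.065),
       C = condition_effect("C", 0.031),
       D = condition_effect("D", 0.047))
}

#' Random target gesture sequence
#'
#' Uniform i.i.d. gestures over \{open, rest, close\}, each held for
#' `gesture_duration` seconds; the default 20 gestures of 3 s make a
#' 1-minute test.
#'
#' @param rng_seed integer seed.
#' @param n_gestures number of gestures (default 20).
#' @param gesture_duration seconds per gesture (default 3).
#' @return An object of class `target_sequence` with fields `gestures`
#'   (coded -1/0/+1), `gesture_duration`, `test_duration`.
#' @export
generate_target_sequence <- function(rng_seed, n_gestures = 20,
                                     gesture_duration = 3) {
  if (n_gestures < 1 || n_gestures != round(n_gestures))
    abort_emg("generate_target_sequence: n_gestures must be a positive ",
              "integer")
  if (gesture_duration <= 0)
    abort_emg("generate_target_sequence: gesture_duration must be > 0")
  g <- withr::with_seed(rng_seed,
                        sample(unname(GESTURES), n_gestures, replace = TRUE))
  structure(list(gestures = as.integer(g),
                 gesture_duration = gesture_duration,
                 test_duration = n_gestures * gesture_duration),
            class = "target_sequence")
}

# ---- carrier and envelope helpers -------------------------------------

# Band-limited Gaussian carrier, unit RMS.
emg_carrier <- function(n, fs, band) {
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bp, stats::rnorm(n)))
  r <- sqrt(mean(x^2))
  if (r == 0) x else x / r
}

# Piecewise-constant series from change points; `times` strictly within
# [0, dur). `values` has one more element than... no: values[i] holds from
# times[i] to times[i+1]; times[1] must be 0.
step_series <- function(times, values, n, fs) {
  out <- numeric(n)
  idx <- pmin(pmax(round(times * fs), 0), n) + 1L
  idx <- c(idx, n + 1L)
  for (i in seq_along(values)) {
    if (idx[i] < idx[i + 1]) out[idx[i]:(idx[i + 1] - 1L)] <- values[i]
  }
  out
}

# Linear-ramp smoothing: causal moving average over ramp_s turns steps
# into trapezoids with ramp_s rise/fall.
ramp_smooth <- function(x, fs, ramp_s) {
  w <- max(1L, as.integer(round(ramp_s * fs)))
  if (w == 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1,
                                method = "convolution"))
  # the causal filter leaves NA for the first w-1 samples; use the partial
  # (shortened-window) means there instead
  cs <- cumsum(x)
  y[seq_len(w - 1L)] <- cs[seq_len(w - 1L)] / seq_len(w - 1L)
  y
}

#' Synthetic calibration recording
#'
#' 24 s, three 8 s phases: rest, maximal finger flexion (FDS burst at
#' `mvc_fds`), maximal finger extension (ED burst at `mvc_ed`). Bursts are
#' band-limited Gaussian carriers amplitude-modulated by trapezoidal
#' envelopes; 50 Hz interference and slow drift are added on top.
#'
#' @param profile a [subject_profile()].
#' @param rng_seed integer seed.
#' @param sp a [signal_params()].
#' @return A [raw_recording()] of kind `"calibration"` (4800
#'   samples/channel at 200 Hz).
#' @export
generate_calibration_recording <- function(profile, rng_seed,
                                           sp = signal_params()) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- 200
  n <- 24L * fs
  pb <- default_phase_bounds()
  withr::with_seed(derive_seed(rng_seed, 7), {
    t <- emg_times(n, fs)
    env_ed <- step_series(c(0, pb["extension", "from"]),
                          c(profile$rest_level_ed, 1), n, fs) * profile$mvc_ed
    env_ed[t >= pb["extension", "to"]] <- 0 # recording ends with the phase
    env_fds <- step_series(c(0, pb["flexion", "from"], pb["flexion", "to"]),
                           c(profile$rest_level_fds, 1,
                             profile$rest_level_fds), n, fs) * profile$mvc_fds
    env_ed <- ramp_smooth(env_ed, fs, sp$ramp_s)
    env_fds <- ramp_smooth(env_fds, fs, sp$ramp_s)
    phase <- stats::runif(2, 0, 2 * pi)
    mk <- function(env, mvc, ph) {
      y <- emg_carrier(n, fs, sp$carrier_band) * env
      if (sp$interference_amp > 0)
        y <- y + sp$interference_amp * mvc *
          sin(2 * pi * sp$interference_hz * t + ph)
      if (sp$drift_amp > 0)
        y <- y + sp$drift_amp * mvc * sin(2 * pi * sp$drift_hz * t + ph / 2)
      y
    }
    raw_recording(mk(env_ed, profile$mvc_ed, phase[1]),
                  mk(env_fds, profile$mvc_fds, phase[2]),
                  sampling_rate = fs, kind = "calibration")
  })
}

# ---- behavioral trial model -------------------------------------------

# Per-trial event schedule: the subject's state timeline. Each row is a
# change point: time (s), state, and the ED/FDS activation amplitudes (MVC
# fraction, on top of rest tone) holding from that time on.
build_trial_schedule <- function(profile, target, effect, rng_seed,
                                 sp = signal_params()) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(target, "target_sequence"),
            inherits(effect, "condition_effect"))
  ng <- length(target$gestures)
  gd <- target$gesture_duration
  p_err <- min(1, effect$error_prob * (0.4 + 1.2 * profile$skill))
  withr::with_seed(derive_seed(rng_seed, 13), {
    delays <- stats::rnorm(ng, profile$response_delay_mean + effect$extra_delay,
                           profile$response_delay_sd)
    if (profile$response_delay_sd == 0) {
      delays <- rep(profile$response_delay_mean + effect$extra_delay, ng)
      if (delays[1] > 0) delays <- pmin(pmax(delays, 0.05), 1.5)
    } else {
      delays <- pmin(pmax(delays, 0.05), 1.5)
    }
    is_err <- stats::runif(ng) < p_err
    err_type <- sample(sp$error_types, ng, replace = TRUE)
    err_dur <- stats::runif(ng, sp$error_dur_range[1], sp$error_dur_range[2])
    # amplitude jitters per gesture (and per error episode)
    j <- matrix(stats::rlnorm(4 * ng, 0, sp$amp_jitter_sd), ncol = 4)
    wrong_pick <- sample(c(-1L, 1L), ng, replace = TRUE) # for REST targets
    times <- 0; states <- "rest"; amp_ed <- 0; amp_fds <- 0
    add <- function(tm, st, ae, af) {
      times <<- c(times, tm); states <<- c(states, st)
      amp_ed <<- c(amp_ed, ae); amp_fds <<- c(amp_fds, af)
    }
    amps_for <- function(code, jit_ed, jit_fds, weak = FALSE) {
      lvl <- if (weak) sp$weak_level else sp$contraction_level
      if (code == GESTURES[["open"]]) c(lvl * jit_ed, 0)
      else if (code == GESTURES[["close"]]) c(0, lvl * jit_fds)
      else c(0, 0)
    }
    for (g in seq_len(ng)) {
      t0 <- (g - 1) * gd + delays[g]
      tgt <- target$gestures[g]
      if (is_err[g]) {
        et <- err_type[g]
        if (et == "wrong_muscle") {
          wrong <- if (tgt == 0L) wrong_pick[g] else -tgt
          a <- amps_for(wrong, j[g, 1], j[g, 2])
          add(t0, "error_wrong", a[1], a[2])
        } else if (et == "co_contraction") {
          add(t0, "error_co",
              sp$contraction_level * j[g, 1], sp$contraction_level * j[g, 2])
        } else { # weak / sub-threshold activation
          a <- amps_for(tgt, j[g, 1], j[g, 2], weak = TRUE)
          add(t0, "error_weak", a[1], a[2])
        }
        a <- amps_for(tgt, j[g, 3], j[g, 4])
        add(t0 + err_dur[g], state_name(tgt), a[1], a[2])
      } else {
        a <- amps_for(tgt, j[g, 1], j[g, 2])
        add(t0, state_name(tgt), a[1], a[2])
      }
    }
    keep <- times < target$test_duration
    data.frame(time = times[keep], state = states[keep],
               amp_ed = amp_ed[keep], amp_fds = amp_fds[keep],
               stringsAsFactors = FALSE)
  })
}

state_name <- function(code) names(GESTURES)[match(code, GESTURES)]

#' Behavioral simulation of the recognized gesture series
#'
#' Fast path for Monte-Carlo work: samples the subject's state timeline
#' (response delays, injected control errors) at 20 Hz and applies the
#' threshold classifier to the idealized activation levels, bypassing the
#' 200 Hz EMG synthesis and conditioning chain. The same per-gesture
#' delay/error schedule drives [generate_trial_recording()], so the two
#' paths agree up to envelope-estimation noise and chain latency.
#'
#' @param profile a [subject_profile()].
#' @param target a [target_sequence()].
#' @param effect a [condition_effect()].
#' @param rng_seed integer seed.
#' @param sp a [signal_params()].
#' @param rate output rate (default 20 Hz).
#' @return A [gesture_series()] with `role = "recognized"`.
#' @export
simulate_recognized_series <- function(profile, target, effect, rng_seed,
                                       sp = signal_params(), rate = 20) {
  sch <- build_trial_schedule(profile, target, effect, rng_seed, sp)
  n <- as.integer(round(target$test_duration * rate))
  t <- emg_times(n, rate)
  seg <- findInterval(t, sch$time)
  nemg_ed <- profile$rest_level_ed + sch$amp_ed[seg]
  nemg_fds <- profile$rest_level_fds + sch$amp_fds[seg]
  vals <- classify_sample(nemg_ed, nemg_fds,
                          profile$rest_level_ed + 0.1,
                          profile$rest_level_fds + 0.1)
  gesture_series(vals, sampling_rate = rate, role = "recognized")
}

#' Synthetic trial recording
#'
#' 60 s two-channel raw sEMG for one test: the subject activates ED during
#' OPEN targets and FDS during CLOSE targets, each transition delayed by a
#' draw from the subject's response-delay distribution (shifted by the
#' condition's `extra_delay`); with probability `effect$error_prob` per
#' gesture (scaled by subject skill) an error episode is injected — wrong
#' muscle, co-contraction, or sub-threshold activation, chosen uniformly —
#' before the subject corrects to the target. Carriers, interference and
#' drift are as in [generate_calibration_recording()].
#'
#' @inheritParams simulate_recognized_series
#' @return A [raw_recording()] of kind `"trial"`.
#' @export
generate_trial_recording <- function(profile, target, effect, rng_seed,
                                     sp = signal_params()) {
  fs <- 200
  n <- as.integer(round(target$test_duration * fs))
  if (n < fs)
    abort_emg("generate_trial_recording: target duration inconsistent ",
              "with a >= 1 s recording")
  sch <- build_trial_schedule(profile, target, effect, rng_seed, sp)
  withr::with_seed(derive_seed(rng_seed, 29), {
    t <- emg_times(n, fs)
    env_ed <- ramp_smooth(
      (profile$rest_level_ed + step_series(sch$time, sch$amp_ed, n, fs)) *
        profile$mvc_ed, fs, sp$ramp_s)
    env_fds <- ramp_smooth(
      (profile$rest_level_fds + step_series(sch$time, sch$amp_fds, n, fs)) *
        profile$mvc_fds, fs, sp$ramp_s)
    phase <- stats::runif(2, 0, 2 * pi)
    mk <- function(env, mvc, ph) {
      y <- emg_carrier(n, fs, sp$carrier_band) * env
      if (sp$interference_amp > 0)
        y <- y + sp$interference_amp * mvc *
          sin(2 * pi * sp$interference_hz * t + ph)
      if (sp$drift_amp > 0)
        y <- y + sp$drift_amp * mvc * sin(2 * pi * sp$drift_hz * t + ph / 2)
      y
    }
    raw_recording(mk(env_ed, profile$mvc_ed, phase[1]),
                  mk(env_fds, profile$mvc_fds, phase[2]),
                  sampling_rate = fs, kind = "trial")
  })
}

#' Simulate a null results table
#'
#' Draws a balanced subjects-by-tests table of L2 scores with no condition
#' or order effect: score = grand mean + subject effect + residual noise.
#' Default variance components match the scale of a healthy-cohort
#' experiment (between-subject sd 0.49, residual sd 0.53 around a grand
#' mean of 3.2). Used to calibrate the inference stage under the null.
#'
#' @param n_subjects cohort size (default 18).
#' @param seed integer seed.
#' @param mu grand mean.
#' @param sd_subject between-subject sd.
#' @param sd_resid residual sd.
#' @return A `data.frame` with columns `subject_id`, `test`, `order`,
#'   `d_l2` (the ResultsTable layout).
#' @export
simulate_null_results_table <- function(n_subjects = 18, seed = 1,
                                        mu = 3.2, sd_subject = 0.49,
                                        sd_resid = 0.53) {
  tests <- c("A", "B", "C", "D")
  withr::with_seed(derive_seed(seed, 43), {
    subj_eff <- stats::rnorm(n_subjects, 0, sd_subject)
    rows <- lapply(seq_len(n_subjects), function(s) {
      ord <- sample(4)
      data.frame(subject_id = s, test = tests,
                 order = ord,
                 d_l2 = pmax(0, mu + subj_eff[s] +
                               stats::rnorm(4, 0, sd_resid)))
    })
    do.call(rbind, rows)
  })
}
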