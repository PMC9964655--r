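test_that("target sequences have the protocol structure and are seeded", {
  ts <- generate_target_sequence(123)
  expect_length(ts$gestures, 20)
  expect_equal(ts$test_duration, 60)
  expect_true(all(ts$gestures %in% c(-1, 0, 1)))
  expect_identical(generate_target_sequence(123)$gestures, ts$gestures)
  expect_false(identical(generate_target_sequence(124)$gestures,
                         ts$gestures))
  expect_error(generate_target_sequence(1, n_gestures = 0), "positive")
  expect_error(generate_target_sequence(1, gesture_duration = -1), "> 0")
})

test_that("long target sequences are uniform over the three states", {
  ts <- generate_target_sequence(99, n_gestures = 10000)
  freq <- table(factor(ts$gestures, levels = c(-1, 0, 1))) / 10000
  se <- sqrt((1 / 3) * (2 / 3) / 10000) # binomial SE oracle
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("calibration recordings follow the 24 s three-phase protocol", {
  p <- subject_profile(1)
  cal <- generate_calibration_recording(p, 42)
  expect_s3_class(cal, "raw_recording")
  expect_equal(cal$kind, "calibration")
  expect_length(cal$ed, 24 * 200)
  expect_length(cal$fds, 24 * 200)
  # seeded reproducibility: bit-identical recordings
  cal2 <- generate_calibration_recording(p, 42)
  expect_identical(cal$ed, cal2$ed)
  expect_identical(cal$fds, cal2$fds)
})

test_that("a zero-tone, zero-interference calibration rests at exactly 0", {
  p <- subject_profile(1, rest_level_ed = 0, rest_level_fds = 0)
  cal <- generate_calibration_recording(p, 7, sp = clean_signal_params())
  rest_idx <- which(emg_times(length(cal$ed), 200) < 8 - 0.15) # before ramp
  expect_true(all(cal$ed[rest_idx] == 0))
  expect_true(all(cal$fds[rest_idx] == 0))
})

test_that("after conditioning, the FDS maximum falls in the flexion phase", {
  p <- subject_profile(1)
  cal <- generate_calibration_recording(p, 314)
  rect <- rectify_rms(filter_raw(cal))
  t <- emg_times(length(rect$fds), rect$sampling_rate)
  t_max_fds <- t[which.max(rect$fds)]
  expect_gte(t_max_fds, 8)
  expect_lt(t_max_fds, 16.3) # allow chain latency past the phase edge
  t_max_ed <- t[which.max(rect$ed)]
  expect_gte(t_max_ed, 16)
})

test_that("generated sEMG has in-band carrier power and a visible 50 Hz line", {
  p <- subject_profile(1)
  cal <- generate_calibration_recording(p, 5)
  # 50 Hz interference visible raw, attenuated >= 20 dB by the notch stage
  raw_amp <- tone_amplitude(cal$ed, 50, 200)
  expect_gt(raw_amp, 0.05 * p$mvc_ed)
  filt <- filter_raw(cal)
  filt_amp <- tone_amplitude(filt$ed, 50, 200)
  expect_lt(filt_amp / raw_amp, 10^(-20 / 20))
  # carrier power concentrated in the configured 20-90 Hz band
  flex <- cal$fds[emg_times(length(cal$fds), 200) >= 9 &
                    emg_times(length(cal$fds), 200) < 15]
  spec <- stats::spec.pgram(ts(flex, frequency = 200), taper = 0,
                            plot = FALSE)
  inband <- sum(spec$spec[spec$freq >= 15 & spec$freq <= 95])
  expect_gt(inband / sum(spec$spec), 0.8)
})

test_that("trial recordings have the right shape and are seeded", {
  p <- subject_profile(2)
  tgt <- generate_target_sequence(8)
  eff <- condition_effect("A", 0.1)
  rec <- generate_trial_recording(p, tgt, eff, 55)
  expect_equal(rec$kind, "trial")
  expect_length(rec$ed, 60 * 200)
  rec2 <- generate_trial_recording(p, tgt, eff, 55)
  expect_identical(rec$ed, rec2$ed)
  short <- generate_target_sequence(8, n_gestures = 1,
                                    gesture_duration = 0.001)
  expect_error(generate_trial_recording(p, short, eff, 55), "duration")
})

test_that("a perfect subject is recognized correctly through the full chain", {
  p <- subject_profile(3, rest_level_ed = 0.02, rest_level_fds = 0.02,
                       response_delay_mean = 0, response_delay_sd = 0)
  sp <- clean_signal_params()
  cal <- generate_calibration_recording(p, 21, sp = sp)
  params <- calibrate(cal)
  tgt <- generate_target_sequence(17)
  eff <- condition_effect("C", 0) # error-free
  rec <- generate_trial_recording(p, tgt, eff, 33, sp = sp)
  recog <- classify_series(normalize_emg(rectify_rms(filter_raw(rec)),
                                         params), params)
  t20 <- target_series(tgt)
  sync <- synchronize(t20, recog)
  a <- sync$aligned_target$values
  b <- sync$aligned_recognized$values
  # the chain's rise/fall threshold crossings are not perfectly
  # symmetric, so allow residual mismatch only at transition edges
  mism <- which(a != b)
  expect_lt(length(mism) / length(a), 0.03)
  if (length(mism)) {
    trans <- which(diff(a) != 0)
    expect_true(all(vapply(mism, function(i)
      any(abs(i - trans) <= 3), logical(1))))
  }
})

test_that("behavioral path: a perfect subject reproduces the target exactly", {
  p <- subject_profile(3, response_delay_mean = 0, response_delay_sd = 0)
  tgt <- generate_target_sequence(17)
  recog <- simulate_recognized_series(p, tgt, condition_effect("C", 0), 33,
                                      sp = clean_signal_params())
  expect_identical(recog$values, target_series(tgt)$values)
})

test_that("all-wrong-muscle subjects disagree on every non-rest gesture", {
  p <- subject_profile(4, response_delay_mean = 0, response_delay_sd = 0,
                       skill = 0.5) # skill 0.5 leaves error_prob = 1 intact
  sp <- clean_signal_params(error_types = "wrong_muscle",
                            error_dur_range = c(2.9, 2.9))
  tgt <- generate_target_sequence(23)
  recog <- simulate_recognized_series(p, tgt, condition_effect("A", 1), 44,
                                      sp = sp)
  t20 <- target_series(tgt)$values
  per_gesture <- split(seq_along(t20), rep(seq_len(20), each = 60))
  for (g in seq_len(20)) {
    idx <- per_gesture[[g]]
    if (any(t20[idx] != 0))
      expect_true(any(recog$values[idx] != t20[idx]),
                  label = sprintf("gesture %d disagrees", g))
  }
})

test_that("expected L2 score increases with the condition error rate", {
  score_at <- function(ep, seed) {
    conds <- lapply(list(A = "A", B = "B", C = "C", D = "D"),
                    function(cn) condition_effect(cn, ep))
    res <- run_experiment(run_config(seed = seed, n_subjects = 6,
                                     conditions = conds,
                                     method = "behavioral"))
    mean(res$results$d_l2)
  }
  m <- vapply(1:3, function(s)
    c(score_at(0.0, s), score_at(0.1, s), score_at(0.35, s)), numeric(3))
  # monotone in error_prob for every seed
  expect_true(all(m[2, ] > m[1, ]))
  expect_true(all(m[3, ] > m[2, ]))
})

test_that("subject profiles reject physiologically impossible parameters", {
  expect_error(subject_profile(1, mvc_ed = 0), "MVC")
  expect_error(subject_profile(1, rest_level_ed = 0.2), "rest levels")
  expect_error(subject_profile(1, skill = 1.5), "skill")
  expect_error(condition_effect("E", 0.1), "A, B, C, D")
  expect_error(condition_effect("A", 1.2), "error_prob")
})
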