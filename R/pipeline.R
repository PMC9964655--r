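#' Experiment run configuration
#'
#' One object holds every module-level parameter; the defaults reproduce
#' the study design: 18 subjects, four feedback conditions, per-subject
#' randomized test order, 20 x 3 s gestures per 1-min test, alpha 0.05.
#'
#' @param seed master integer seed; all per-subject and per-trial seeds
#'   are derived from it.
#' @param n_subjects cohort size (default 18).
#' @param conditions named list of [condition_effect()]s (default
#'   [default_condition_effects()]).
#' @param sp a [signal_params()].
#' @param n_gestures,gesture_duration test structure (default 20 x 3 s).
#' @param order_mode `"random"` (independent uniform permutation per
#'   subject) or `"latin"` (balanced Latin square, sharper order-effect
#'   inference; requires `n_subjects` divisible by 4).
#' @param method `"emg"` (full 200 Hz synthesis + conditioning chain) or
#'   `"behavioral"` (direct 20 Hz simulation, for Monte-Carlo work).
#' @param alpha significance level for the inference stage.
#' @param max_lag_s synchronization search window (s).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 18,
                       conditions = default_condition_effects(),
                       sp = signal_params(), n_gestures = 20,
                       gesture_duration = 3,
                       order_mode = c("random", "latin"),
                       method = c("emg", "behavioral"),
                       alpha = 0.05, max_lag_s = 2.0) {
  order_mode <- match.arg(order_mode)
  method <- match.arg(method)
  if (n_subjects < 2)
    abort_emg("run_config: need at least 2 subjects")
  if (!identical(sort(names(conditions)), c("A", "B", "C", "D")))
    abort_emg("run_config: conditions must be a named list A, B, C, D")
  if (order_mode == "latin" && n_subjects %% 4 != 0)
    abort_emg("run_config: latin-square order mode needs n_subjects ",
              "divisible by 4")
  structure(list(seed = seed, n_subjects = n_subjects,
                 conditions = conditions, sp = sp,
                 n_gestures = n_gestures,
                 gesture_duration = gesture_duration,
                 order_mode = order_mode, method = method,
                 alpha = alpha, max_lag_s = max_lag_s),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  x <- unclass(config)
  x$conditions <- lapply(x$conditions, unclass)
  x$sp <- unclass(x$sp)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  conds <- lapply(x$conditions, function(cn)
    condition_effect(cn$condition, cn$error_prob, cn$extra_delay))
  sp <- do.call(signal_params, x$sp)
  run_config(seed = x$seed, n_subjects = x$n_subjects, conditions = conds,
             sp = sp, n_gestures = x$n_gestures,
             gesture_duration = x$gesture_duration,
             order_mode = x$order_mode, method = x$method,
             alpha = x$alpha, max_lag_s = x$max_lag_s)
}

# test order for one subject
subject_test_order <- function(config, subject_idx, seed) {
  tests <- c("A", "B", "C", "D")
  if (config$order_mode == "latin") {
    # cyclic balanced rows: subject s gets row (s mod 4) of a 4x4 square
    r <- (subject_idx - 1) %% 4
    tests[((seq_len(4) - 1 + r) %% 4) + 1]
  } else {
    withr::with_seed(seed, sample(tests))
  }
}

#' Run the full experiment end to end
#'
#' For every subject: draw a profile, generate and process a calibration
#' recording, then run the four tests in the subject's randomized order —
#' generate the target sequence and trial recording, condition and
#' normalize the EMG, classify gestures, synchronize against the target
#' and score the L2 distance. Finishes with the inference stage (additive
#' ANOVA, Duncan's multiple range test, homoscedasticity check). Under
#' `method = "behavioral"` the recognized series is simulated directly at
#' 20 Hz from the same delay/error schedule, skipping EMG synthesis.
#'
#' @param config a [run_config()].
#' @param out_dir if non-NULL, write per-trial artifacts (raw recordings,
#'   target/recognized gesture CSVs, per-trial JSON), the cohort results
#'   CSV and calibration JSONs there.
#' @param profiles optional list of [subject_profile()]s to use instead of
#'   drawing a random cohort (length `n_subjects`).
#' @param quiet suppress per-trial log lines.
#' @return List of class `experiment_result`: `results` (long-format
#'   table: `subject_id`, `test`, `order`, `t_d_seconds`, `d_l2`),
#'   `anova`, `duncan`, `homoscedasticity`, `calibrations`, `config`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           profiles = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(profiles) && length(profiles) != config$n_subjects)
    abort_emg("run_experiment: profiles must match n_subjects")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  calibs <- list()
  for (s in seq_len(config$n_subjects)) {
    seed_s <- derive_seed(config$seed, s)
    profile <- if (is.null(profiles)) {
      generate_subject_profiles(1, derive_seed(seed_s, 1))[[1]]
    } else {
      profiles[[s]]
    }
    profile$subject_id <- s
    params <- NULL
    if (config$method == "emg") {
      calib_rec <- generate_calibration_recording(
        profile, derive_seed(seed_s, 2), sp = config$sp)
      params <- tryCatch(calibrate(calib_rec), error = function(e)
        abort_emg("subject ", s, " calibration failed: ",
                  conditionMessage(e)))
      calibs[[s]] <- params
      if (!is.null(out_dir))
        write_calibration_json(params, file.path(
          out_dir, sprintf("subject%02d_calibration.json", s)))
    }
    ord <- subject_test_order(config, s, derive_seed(seed_s, 3))
    for (k in seq_along(ord)) {
      test <- ord[k]
      effect <- config$conditions[[test]]
      tgt <- generate_target_sequence(derive_seed(seed_s, 10, k),
                                      n_gestures = config$n_gestures,
                                      gesture_duration =
                                        config$gesture_duration)
      trial_seed <- derive_seed(seed_s, 20, k)
      recog <- tryCatch({
        if (config$method == "emg") {
          rec <- generate_trial_recording(profile, tgt, effect, trial_seed,
                                          sp = config$sp)
          if (!is.null(out_dir))
            write_recording_csv(rec, file.path(
              out_dir, sprintf("subject%02d_test%s.csv", s, test)))
          nemg <- normalize_emg(rectify_rms(filter_raw(rec)), params)
          classify_series(nemg, params)
        } else {
          simulate_recognized_series(profile, tgt, effect, trial_seed,
                                     sp = config$sp)
        }
      }, error = function(e)
        abort_emg("subject ", s, " test ", test, " failed: ",
                  conditionMessage(e)))
      tgt20 <- target_series(tgt)
      ev <- evaluate_trial(tgt20, recog, max_lag_s = config$max_lag_s)
      if (!quiet)
        message(sprintf("subject %02d test %s (order %d): T_d = %.2f s, ",
                        s, test, k, ev$t_d_seconds),
                sprintf("d_L2 = %.3f", ev$d_l2))
      if (!is.null(out_dir)) {
        base <- sprintf("subject%02d_test%s_order%d", s, test, k)
        write_gesture_csv(tgt20, file.path(out_dir,
                                           paste0(base, "_target.csv")))
        write_gesture_csv(recog, file.path(out_dir,
                                           paste0(base, "_recognized.csv")))
        jsonlite::write_json(
          list(subject = s, test = test, order = k,
               t_d_seconds = ev$t_d_seconds, d_l2 = ev$d_l2),
          file.path(out_dir, paste0(base, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, test = test, order = k,
        t_d_seconds = ev$t_d_seconds, d_l2 = ev$d_l2)
    }
  }
  results <- do.call(rbind, rows)
  anova <- fit_additive_anova(results)
  duncan <- duncan_mrt(results, anova, alpha = config$alpha)
  homo <- check_homoscedasticity(results, alpha = config$alpha)
  if (!is.null(out_dir))
    utils::write.csv(results, file.path(out_dir, "cohort_results.csv"),
                     row.names = FALSE)
  structure(list(results = results, anova = anova, duncan = duncan,
                 homoscedasticity = homo, calibrations = calibs,
                 config = config),
            class = "experiment_result")
}

#' Re-analyze externally provided gesture series
#'
#' Runs only the scoring and inference stages (synchronize, L2 distance,
#' ANOVA, Duncan, homoscedasticity) on a directory of target/recognized
#' gesture CSVs named `subjectNN_testT_orderK_{target,recognized}.csv` —
#' the layout [run_experiment()] writes, and the dialect external trial
#' records can be mapped to.
#'
#' @param trials_dir directory of gesture CSV pairs.
#' @param alpha significance level.
#' @param max_lag_s synchronization search window (s).
#' @return List with `results`, `anova`, `duncan`, `homoscedasticity`.
#' @export
reanalyze <- function(trials_dir, alpha = 0.05, max_lag_s = 2.0) {
  files <- list.files(trials_dir, pattern = "_target\\.csv$")
  if (length(files) == 0L)
    abort_emg("reanalyze: no *_target.csv files found in ", trials_dir)
  meta <- regmatches(files, regexec(
    "^subject([0-9]+)_test([A-D])_order([0-9]+)_target\\.csv$", files))
  bad <- vapply(meta, length, integer(1)) != 4
  if (any(bad))
    abort_emg("reanalyze: unrecognized file name(s): ",
              paste(utils::head(files[bad], 3), collapse = ", "))
  rows <- lapply(seq_along(files), function(i) {
    m <- meta[[i]]
    rec_file <- file.path(trials_dir, sub("_target\\.csv$",
                                          "_recognized.csv", files[i]))
    if (!file.exists(rec_file))
      abort_emg("reanalyze: missing recognized series for ", files[i])
    tgt <- read_gesture_csv(file.path(trials_dir, files[i]),
                            role = "target")
    recog <- read_gesture_csv(rec_file, role = "recognized")
    ev <- evaluate_trial(tgt, recog, max_lag_s = max_lag_s)
    data.frame(subject_id = as.integer(m[2]), test = m[3],
               order = as.integer(m[4]),
               t_d_seconds = ev$t_d_seconds, d_l2 = ev$d_l2)
  })
  results <- do.call(rbind, rows)
  anova <- fit_additive_anova(results)
  list(results = results, anova = anova,
       duncan = duncan_mrt(results, anova, alpha = alpha),
       homoscedasticity = check_homoscedasticity(results, alpha = alpha))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %d subjects x 4 tests (%s path)>\n",
              x$config$n_subjects, x$config$method))
  means <- tapply(x$results$d_l2, x$results$test, mean)
  sds <- tapply(x$results$d_l2, x$results$test, stats::sd)
  for (tn in names(means))
    cat(sprintf("  test %s: d_L2 = %.2f +/- %.2f\n", tn, means[tn],
                sds[tn]))
  cat(sprintf("  mean T_d = %.2f +/- %.2f s\n",
              mean(x$results$t_d_seconds), stats::sd(x$results$t_d_seconds)))
  cat(sprintf("  ANOVA test-factor p = %.4f\n",
              x$anova$p_value[x$anova$term == "Test"]))
  invisible(x)
}
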