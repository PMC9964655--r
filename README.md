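# emgrehab

Simulation and analysis of threshold-based surface-EMG control for
bilateral hand rehabilitation.

In EMG-driven bilateral therapy, two-channel surface EMG from the healthy
forearm — extensor digitorum (ED, hand opening) and flexor digitorum (FDS,
hand closing) — drives a robotic exoskeleton on the paretic hand. A
real-time algorithm conditions the raw signal, normalizes it against a
calibration, and classifies each sample into one of three gestures. The
scientific question the package is built around: does visual biofeedback of
the processed EMG improve control quality over the kinesthetic feedback of
the moving exoskeleton alone? `emgrehab` provides the full computational
pathway at desk scale — a seeded synthetic cohort, the signal chain, the
classifier, trial scoring, and the inference stage — for methodologists who
want to study or extend this class of controller without hardware.

## The model

Raw EMG at 200 Hz passes through a causal chain: 50 Hz notch (Q = 30) →
10 Hz 2nd-order Butterworth high-pass → trailing 50 ms RMS → 2 Hz low-pass
→ decimation to 20 Hz (rEMG) → division by the calibration MVC (nEMG).
Calibration is 24 s (8 s rest, 8 s maximal flexion, 8 s maximal extension);
MVC is the rEMG maximum and the deactivation thresholds are the rest-phase
nEMG minima plus 0.1:

    epsilon = min_rest nEMG_ED + 0.1,    mu = min_rest nEMG_FDS + 0.1

With A = nEMG_ED > epsilon, B = nEMG_FDS > mu, C = nEMG_ED > nEMG_FDS, the
gesture at each 20 Hz sample is

    REST  = !A & !B
    OPEN  = A & (!B | C)
    CLOSE = B & (!A | !C)

coded Open = −1, Rest = 0, Close = +1. Per one-minute trial (20 cued
gestures of 3 s), the recognized series is synchronized to the target by
raw sliding-dot-product cross-correlation over non-negative lags up to 2 s
(the winning lag is the delay time T_d), and scored with the L2 distance

    d_L2 = sum_i (x*_i − x_i)^2 * T_s,    T_s = 0.05 s.

Cohort tables (subjects × the four feedback conditions A–D) are analyzed
with a sequential additive ANOVA `d_l2 ~ test + order + individual`,
Duncan's multiple range test for pairwise condition comparisons, and a
Levene homoscedasticity check. The methods vignette
(`vignettes/emg-biofeedback-pipeline.Rmd`) documents every design decision,
the synthetic subject model, and known limitations.

## Worked example

Simulate one subject end to end through the full 200 Hz chain:

```r
library(emgrehab)

profile <- generate_subject_profiles(1, seed = 42)[[1]]

# Calibration: 24 s recording -> MVC and thresholds
cal <- calibrate(generate_calibration_recording(profile, rng_seed = 7))
cal
#> <calibration_params: MVC_ED = 2.276 mV, MVC_FDS = 2.940 mV, epsilon = 0.100, mu = 0.100>

# One 1-minute trial under condition A (exoskeleton only, no screen)
target <- generate_target_sequence(rng_seed = 11)
rec <- generate_trial_recording(profile, target, condition_effect("A", 0.062),
                                rng_seed = 12)
nemg <- normalize_emg(rectify_rms(filter_raw(rec)), cal)
recognized <- classify_series(nemg, cal)

ev <- evaluate_trial(target_series(target), recognized)
ev$t_d_seconds   # estimated response delay
#> [1] 0.6
ev$d_l2          # L2 distance to the cued sequence (0 = perfect)
#> [1] 3
```

Run a full 18-subject, four-condition experiment and the inference stage
in one call:

```r
res <- run_experiment(run_config(seed = 20220131))
res$anova
#>         term df    sum_sq  mean_sq  f_value     p_value
#> 1       Test  3  9.607361 3.202454 2.639664 0.060064474
#> 2      Order  3  6.198793 2.066264 1.703145 0.178880399
#> 3 Individual 17 50.431528 2.966560 2.445226 0.007805304
#> 4  Residuals 48 58.233845 1.213205       NA          NA
```

This is the same cohort the analysis scripts below persist to `results/`.

## The analysis workflow

Numbered scripts under `analysis/` reproduce the study from scratch
(`Rscript analysis/01_simulate_and_score.R`, then `02`, then `03`). With
the committed master seed 20220131 they print:

* **01_simulate_and_score.R** — full EMG-chain cohort, 18 subjects × 4
  tests. Mean d_L2 (lower is better): A = 2.99 ± 1.42, B = 2.81 ± 1.28,
  C = 2.15 ± 1.42, D = 2.22 ± 1.06; mean delay T_d = 0.60 ± 0.09 s. The
  ordering matches the built-in condition effects: visual biofeedback
  (C, and D with the screen added to the exoskeleton) outperforms the
  no-screen conditions A and B.
* **02_statistics.R** — ANOVA test-factor p = 0.0601, individual factor
  p = 0.0078 (large between-subject spread, as expected), order n.s.;
  Duncan pairwise C–A p = 0.038, C–B p = 0.095; Levene F = 0.101,
  p = 0.959 (homoscedastic).
* **03_operating_characteristics.R** — under the null (no condition
  effect, 500 cohorts) the test-factor p-values are uniform (KS p = 0.53)
  with a 6.8% false-positive rate at alpha = 0.05, and Levene passes 97.6%
  of the time; with a strong planted effect (100 cohorts, condition C
  error rate 0.05 vs 0.30) the test factor is significant and Duncan
  separates C from both A and B in 100% of cohorts.

Outputs land in `results/` (small CSV/JSON); heavyweight per-trial
artifacts and plots go to `scratch/`.

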