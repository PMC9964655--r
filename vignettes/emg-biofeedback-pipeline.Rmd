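---
title: "Methods: simulating and evaluating threshold-based EMG control of a hand exoskeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating threshold-based EMG control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgrehab)
```

## The problem

In EMG-driven bilateral hand rehabilitation, the muscle activity of the
healthy forearm — the extensor digitorum (ED), which opens the hand, and the
flexor digitorum (FDS), which closes it — drives a robotic exoskeleton on the
paretic hand. The user follows a cued sequence of gestures (rest, open,
close); a real-time threshold algorithm recognizes the gesture from
two-channel surface EMG and replicates it on the robot. The experimental
question is whether feeding the processed EMG back to the user visually
(two bars showing the instantaneous normalized activation of each muscle)
improves control, compared with the kinesthetic feedback of the moving
exoskeleton. `emgrehab` implements the full computational pathway of such an
experiment at desk scale: a seeded synthetic cohort, the signal-conditioning
chain, calibration, the gesture classifier, trial scoring, and the
inference stage.

## Signal conditioning

Raw EMG is sampled at 200 Hz. The chain is, per channel:

1. **50 Hz notch** — 2nd-order constrained-poles biquad, quality factor
   Q = 30, removing mains interference;
2. **10 Hz high-pass** — 2nd-order Butterworth, removing drift and motion
   artifact;
3. **RMS rectification** — trailing root-mean-square over a 50 ms window
   (10 samples at 200 Hz), with shortened windows at the start;
4. **2 Hz low-pass** — 2nd-order Butterworth envelope smoothing;
5. **decimation** — every 10th sample kept, giving the 20 Hz rectified
   series (rEMG); the 2 Hz low-pass already bounds the bandwidth far below
   the 10 Hz output Nyquist, so no separate anti-alias stage is needed;
6. **MVC normalization** — division by the per-muscle maximal voluntary
   contraction from calibration, giving nEMG in MVC units.

All filters are applied causally (forward only). The reference system runs
sample-by-sample on a microcontroller; zero-phase filtering would
misrepresent its latency, which matters because the evaluation explicitly
measures delay. Filter families and orders are conventional choices — the
algorithm is defined by its cutoffs and rates, not by a specific filter
realization. nEMG is *not* clipped at 1: trial contractions can exceed the
calibration maximum, and the thresholds are referenced to rest-phase
minima, so clipping would only discard information.

Chain latency is dominated by the 2 Hz low-pass; a step activation reaches
90% of steady state in well under 1 s (tested), so recognition keeps up
with the 3 s gesture cadence.

## Calibration

The 24 s calibration has three 8 s phases: rest, maximal flexion, maximal
extension. `MVC` per muscle is the maximum of its rEMG over the whole
calibration; the deactivation thresholds are

$$\varepsilon = \min_{\text{rest}} \mathrm{nEMG}_{ED} + 0.1, \qquad
  \mu = \min_{\text{rest}} \mathrm{nEMG}_{FDS} + 0.1 ,$$

computed on the 20 Hz nEMG for consistency with the trial chain. The rest
phase is taken as the nominal first 8 s — no onset detection. Because the
causal chain starts from zero, the rest-phase minimum typically sits very
close to zero, so thresholds land near the 0.1 floor; this floor is a hard
invariant (nEMG is non-negative). A noisy rest phase that pushes a
threshold past 1 MVC is reported as a calibration-quality warning rather
than an error. Calibration is scale-invariant by construction: a global
gain change rescales MVC but leaves thresholds and all recognized gestures
unchanged (tested).

## Gesture recognition

With $A \equiv \mathrm{nEMG}_{ED} > \varepsilon$,
$B \equiv \mathrm{nEMG}_{FDS} > \mu$ and
$C \equiv \mathrm{nEMG}_{ED} > \mathrm{nEMG}_{FDS}$ (all strict):

$$\mathrm{REST} = \bar A \bar B, \qquad
  \mathrm{OPEN} = A(\bar B + C), \qquad
  \mathrm{CLOSE} = B(\bar A + \bar C).$$

Exactly one output is true for every boolean combination (verified by
exhaustive enumeration). Gestures are coded Open = −1, Rest = 0,
Close = +1, so an open/close confusion is twice as far apart as either is
from rest. Two tie-break conventions are fixed deliberately: equality with
a threshold counts as *not* exceeding it, and an exact tie
$\mathrm{nEMG}_{ED} = \mathrm{nEMG}_{FDS}$ with both muscles active makes
$C$ false and yields CLOSE — the literal reading of the strict-inequality
definitions. The parenthesization of OPEN/CLOSE follows the prose
definition of the algorithm (each muscle must dominate when both exceed
their thresholds); it is also the only reading under which the three
outputs are mutually exclusive and complete. Classification is purely
sample-wise at 20 Hz: no hysteresis or dwell-time debouncing.

## Trial scoring

The recognized series lags the target (user response time plus processing).
Synchronization uses the raw sliding-dot-product cross-correlation

$$r_{xy}(h) = \sum_{n=0}^{N-h-1} x(n+h)\, y(n),$$

maximized over non-negative lags up to 2 s (recognition physically lags
the target; observed delays sit well inside this window). Ties go to the
smallest lag; all-constant series fall back to zero delay with a warning.
The delay time $T_d$ is a single constant per test. After shifting the
recognized series back by the winning lag, the target is truncated at the
end to the common length $n = (60 - T_d)/T_s$ samples and the score is

$$d_{L2} = \sum_i (x^*_i - x_i)^2 \, T_s, \qquad T_s = 0.05\ \mathrm{s}.$$

$d_{L2} = 0$ iff the aligned series agree everywhere, and
$d_{L2} \le 4 n T_s$.

## The synthetic cohort

No biophysical motor-unit model is attempted. The generator produces the
*minimal* signal that exercises every stage of the chain:

* **carrier** — zero-mean Gaussian noise band-passed to 20–90 Hz, unit RMS,
  amplitude-modulated by the activation envelope;
* **envelope** — piecewise-constant activation with 100 ms linear
  rise/fall (trapezoids); voluntary contractions at 0.6 MVC with lognormal
  per-gesture amplitude jitter (sd 0.15 on the log scale); rest tone drawn
  per subject from U(0.01, 0.05) MVC, strictly below the threshold floor;
* **contaminants** — 50 Hz sinusoid at 10% of MVC and 0.5 Hz drift at 5% of
  MVC, which the notch and high-pass stages must remove (tested: ≥ 20 dB
  attenuation of the 50 Hz line, < 5% RMS effect on the envelope).

Subject behavior is modeled per gesture: the transition to each cued
gesture is delayed by a draw from a normal distribution (per-subject mean
U(0.30, 0.55) s, sd U(0.05, 0.12) s) truncated to [0.05, 1.5] s; with a
per-gesture error probability an error episode is injected — wrong muscle,
co-contraction, or sub-threshold activation, chosen uniformly — lasting
U(0.25, 0.75) s before the subject corrects. The condition effect is a
per-condition error probability (and optionally extra delay). Defaults are
ordered C < D < A ≈ B (0.031, 0.047, 0.062, 0.065), scaled by a
per-subject skill multiplier in [0.4, 1.6]: visual biofeedback gives the
earliest corrective information, kinesthetic feedback the latest. The
magnitudes were chosen once, from the expected per-error contribution to
$d_{L2}$ (≈ 0.9 per error episode, ≈ 2 from delay jitter per test), to
land mean scores in a plausible 2–3.5 range for a 1-minute test.

The same per-gesture schedule drives two paths: the **EMG path**
synthesizes the full 200 Hz recording and runs the complete chain, and the
**behavioral path** samples the schedule directly at 20 Hz and applies the
classifier to the idealized activation levels. The behavioral path is used
for Monte-Carlo operating characteristics (hundreds of cohorts); the EMG
path is the default for the experiment itself.

What the generator does **not** emulate: real sEMG spectra and amplitude
statistics (the millivolt scales are conventional placeholders), muscular
fatigue, electrode-placement variability, electromechanical delay beyond a
lumped response-time constant, learning across tests, or any actuator
dynamics. Passing tests therefore demonstrate the correctness and
calibration of the *pipeline*, not fidelity to any particular subject
population.

One consequence of the causal chain worth stating: even a perfect,
zero-delay subject does not reproduce the target *exactly* through the EMG
path, because threshold crossings on rising versus falling envelope edges
occur at slightly different offsets (the 100 ms ramp plus 2 Hz smoothing).
After synchronization this leaves at most a couple of samples of mismatch
around some transitions; the behavioral path is exact. Tests assert each
path's actual property.

## Inference stage

The cohort table (18 subjects × 4 tests, one row per trial) is analyzed
with the additive model

`d_l2 ~ test + order + individual`

using sequential (Type I) sums of squares in that order; with the balanced
subjects-by-tests design, test and individual are orthogonal. The
individual factor blocks between-subject variability; residual df for the
default design is 48. Degenerate inputs — missing cells, saturated models
(e.g. 2 subjects), order randomizations that exactly confound order with
test — are rejected with explicit errors.

Pairwise condition comparisons use Duncan's multiple range test, built
directly on the studentized range distribution: a pair of means separated
by $r$ ranks separates at level $\alpha$ when its standardized difference
exceeds the range quantile at the protection level $1-(1-\alpha)^{r-1}$
with the residual df. Reported pairwise p-values invert this criterion
numerically (root-finding on $\alpha$); the closed-form inverse
$p = 1-(1-P)^{1/(r-1)}$, with $P$ the studentized-range exceedance
probability, serves as an independent oracle in the tests. Two groups
reduce exactly to a pooled-variance t-test.

Homoscedasticity across the four test groups is checked with Levene's test
(median-centered; Bartlett available behind a flag); all-zero within-group
spread is reported as a degenerate case with a warning.

## Numerical and design choices

* Sample indexing is 0-based with time origin at the first sample; the
  20 Hz series has timestamps $k/20$ s.
* All randomness flows through explicitly passed integer seeds;
  per-subject/per-trial seeds are derived from the master seed by integer
  mixing modulo $2^{31}-1$, so cohorts are bit-reproducible and any trial
  can be regenerated in isolation.
* Test order per subject defaults to an independent uniform permutation; a
  balanced Latin-square mode is available for sharper order-effect
  inference (it makes test and order orthogonal).
* Problem sizes for the Monte-Carlo suites: 500 table-level null cohorts
  for p-value calibration and 100 behavioral cohorts for effect recovery —
  enough for ~1% precision on the rates being checked while keeping a full
  run of the suite in the tens of seconds.

## Known limitations

* The error taxonomy (wrong muscle / co-contraction / weak activation) is
  a modeling invention; real subjects' errors are not categorized in these
  terms, and only aggregate performance is comparable.
* $T_d$ is constant per test by construction of the scorer; gesture-level
  delay variation shows up as score, not as delay.
* The simulated between-subject spread is driven by a single skill scalar
  and the delay distribution; real cohorts have richer structure, so
  simulated variance components should not be read as population
  estimates.
* The pipeline analyzes gesture series; it does not model, and cannot
  detect, GUI- or actuator-level failure modes.
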