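---
title: "Estimating blood pressure from PPG pulse morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from PPG pulse morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem

Invasive arterial lines measure blood pressure (BP) continuously but cannot
be used outside critical care; cuffs are non-invasive but intermittent and
obstructive. The photoplethysmogram (PPG) — the optical volume-pulse signal
every pulse oximeter already records — carries morphological information
related to arterial distensibility and vascular tone, and therefore,
indirectly, to BP. `ppgbp` implements a calibration-based machine-learning
pipeline that turns PPG pulse morphology into systolic (SBP) and diastolic
(DBP) estimates and quantifies both absolute accuracy and the ability to
track acute BP changes such as those induced during anesthesia induction.

The pipeline has six stages:

1. **Preprocessing** (`preprocess_recording()`): PPG/arterial-line alignment
   by cross-correlation; zero-phase band-pass filtering (3rd-order
   Butterworth low-pass at 15 Hz, high-pass at 0.5 Hz, each applied
   forward-backward); segmentation into 20-s windows with 50% overlap; beat
   detection; a per-beat signal quality index (SQI); a quality-weighted
   ensemble-average (EA) pulse per window; and a windowed reference BP taken
   as the median of per-beat systolic/diastolic/mean values from the
   arterial signal. Windows are kept only if the EA-pulse SQI is at least
   0.75 and the reference variability (sd/mean of the per-beat series,
   checked for both the SBP and the DBP series) is at most 0.10.
2. **Pulse wave analysis** (`pulse_derivatives()`, `detect_fiducials()`,
   `pulse_features()`): the EA pulse and its first three derivatives —
   velocity (VPG), acceleration (APG) and jerk (JPG) plethysmograms — are
   annotated with fiducial points (systolic peak, dicrotic notch, diastolic
   peak; VPG w/y/z; APG a–e; JPG p0–p3), and morphological features are
   computed: MAP, MSBP, MDBP, ESP, SPTI, DPTI, SEVR, perfusion index (PI),
   heart-rate-corrected augmentation index (AIx75), heart rate, and the
   time and amplitude of every fiducial point, optionally joined with
   age, weight, height and gender.
3. **Calibration pairing** (`build_pairs()`): within each recording, every
   earlier valid window serves once as a calibration measure for every later
   window. A sample concatenates the calibration-segment features, the
   calibration reference BP triplet, the estimation-segment features and the
   demographics; the estimation-segment reference is the training target.
   A calibration-free variant (`build_calibration_free()`) uses only the
   estimation-segment features plus demographics.
4. **Feature selection** (`lasso_select()`): Lasso with the regularization
   weight chosen by subject-stratified 10-fold cross-validation over a
   100-point log grid; `permutation_relevance()` scores each feature by the
   relative increase in the error standard deviation (STDE) when that
   feature is permuted across the test set, averaged over 100 seeded
   permutations.
5. **Regression** (`fit_bp_model()`): Lasso, RBF-kernel support vector
   regression, Gaussian process regression with a squared-exponential
   kernel, and a *flat* control model that predicts the calibration
   reference (or, calibration-free, the training mean). Separate models are
   fitted for SBP and DBP.
6. **Evaluation** (`error_stats()`, `extract_changes()`, `four_quadrant()`,
   `polar_stats()`): mean error (ME) and STDE in mmHg, overall and per
   subject; trending ability on all BP changes of at least 20% of the
   earlier window's reference, via four-quadrant concordance rate and
   Pearson correlation, and polar statistics (angle = deviation from the
   identity line, radius = mean change amplitude), binned into changes
   spanning at most versus more than 3 minutes.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| Low-pass / high-pass cutoffs | 15 / 0.5 | Hz | retain pulse morphology, remove noise and baseline |
| Filter order | 3 per pass | – | standard Butterworth PPG conditioning |
| Window / overlap | 20 / 50% | s / – | enough beats for a stable EA pulse while tracking minute-scale BP swings |
| EA pulse length L | 256 | samples | power of two; preserves 15 Hz content at all physiologic heart rates |
| SQI gate | 0.75 | – | excludes windows whose beats disagree with the template/neighbors |
| Reference variability gate | 0.10 | – | excludes windows where BP moved too much for a single reference value |
| Train fraction | 0.8 | – | subject-level split, stratified on per-subject mean SBP |
| CV folds | 10 | – | subject-stratified; no subject spans folds |
| Permutation repeats | 100 | – | stabilizes the relevance mean |
| Change threshold | 20% | – | clinically acute changes |
| Trend bin edge | 180 | s | rapid vs slow changes |
| AIx75 slope k | 0.48 | %/bpm | conventional linear heart-rate normalization of the augmentation index |

## Design choices

Several steps of the published approach sit inside proprietary software and
are unspecified; the package makes them concrete and documents them:

* **Beat detection** uses slope-based foot detection: local maxima of the
  first derivative above an adaptive threshold locate systolic upstrokes,
  and the preceding signal minimum (searched over 0.3 s) is the pulse foot,
  with a 0.24 s refractory period. The same detector segments the arterial
  waveform.
* **SQI** is the equal-weight mean of the beat's Pearson correlation with
  the recording's median-beat template and the mean correlation with its
  neighboring beats, each rescaled from [-1, 1] to [0, 1] — the simplest
  formula honoring both similarity criteria.
* **Dicrotic notch** is read at the VPG z-wave (the velocity rebound between
  the systolic and reflected waves). The APG e-wave, the other common
  convention, proved unreliable on two-Gaussian morphology, where the
  detected e-wave can land at the reflected-wave center rather than at the
  notch; the z-wave marks the transition robustly for both peak-type and
  shoulder-type reflected waves. The diastolic peak is the first PPG local
  maximum after the notch, falling back to the reflected-wave shoulder
  (a local maximum of the VPG below zero). A pulse with no reflected wave
  at all (e.g. a single Gaussian) yields no notch and no diastolic point,
  and such windows are dropped from the learning tables.
* **Extrema pruning**: all fiducial searches discard adjacent
  local-extremum pairs whose amplitude gap is below 2% of the signal range,
  which removes residual-noise ripples while preserving the max/min
  alternation. Derivatives are estimated by central differences followed by
  a 25 ms Savitzky–Golay smoothing window (time-referenced, so behavior
  does not depend on the resampling rate).
* **Features on the foot-zeroed pulse**: the high-pass filter leaves the EA
  pulse zero-mean, so pressure-time-index analogs (MAP, SPTI, DPTI, ...)
  are computed after re-zeroing the pulse at its minimum. The perfusion
  index uses the unfiltered window mean as its DC term, which the
  preprocessing stage retains per window; its AC term is the pulsatile
  amplitude (half the peak-to-trough swing).
* **AIx inflection** is read at the APG d-wave time by default
  (configurable), a standard choice for the reflected-wave onset.
* **SVR hyperparameters** (kernel scale, box constraint, insensitive-band
  width) are tuned by a seeded 30-draw randomized search over log-uniform
  ranges with subject-stratified 10-fold CV; **GPR** hyperparameters
  (shared length-scale, signal and noise standard deviations) maximize the
  log marginal likelihood via L-BFGS-B. Kernel models are trained on seeded
  subsamples (tuning 1000 rows, final fits 3000 for SVR / 800 for GPR) —
  kernel methods scale between quadratically and cubically in the sample
  count, and the calibration-pair table runs to ~10^5 rows; the subsample
  sizes were fixed up front as the intended problem size.
* **Stratified split**: subjects are binned into quartiles of per-subject
  mean SBP and sampled proportionally; up to 20 seeded draws are attempted
  and the best-balanced kept (train/test mean-SBP gap below half the pooled
  SD in practice).
* **Zero estimated change** in the four-quadrant analysis counts as
  discordant unless the reference change is also zero; exactly-20% changes
  are included; the relative threshold uses the earlier window's reference
  (the only causal choice). Polar pairs with negative mean change are
  mirrored through the origin so angles compare like-direction changes.

## The synthetic cohort

No public dataset pairs finger PPG with an arterial line during anesthesia
induction, so the package ships a seeded generator (`synth_cohort()`) that
emulates the study conditions end to end: 40 subjects, 9–19 min recordings
at 125 Hz, per-subject mean SBP drawn from N(124.3, 24.8²) truncated to
(90, 195) mmHg and mean DBP around 63 ± 10 mmHg, an induction drop of
20–45% of baseline over 1–3 minutes with partial, bumpy recovery and a slow
AR(1) drift. Demographics are drawn near the same cohort's distributions
(age 62 ± 13 y, weight 73 ± 13 kg, height 170 ± 10 cm, ~53% male).

Each beat is a two-Gaussian pulse whose parameters are a **documented
closed-form function of the current BP state** (`pulse_from_bp()`): with
s = (SBP−120)/25, d = (DBP−65)/10 and period T, the reflected (diastolic)
wave has amplitude 0.30 + 0.09·s and center (0.47 − 0.03·s)·T, and the
systolic width is (0.065 − 0.006·d)·T. Higher SBP therefore produces a
larger, earlier reflected wave; higher DBP a steeper upstroke. The slopes
are deliberately gentle enough that the reflected wave never merges into
the systolic peak over the physiologic range, keeping the planted link
globally linear and recoverable. Per-subject nuisance effects — PPG gain
(sd 0.08), DC offset, a diastolic-amplitude offset (sd 0.06) and a timing
offset (sd 0.015 of T) — emulate inter-subject morphology variability;
they are exactly what a calibration measure corrects, which is how the
generator reproduces the qualitative calibration benefit. The arterial
channel is the same beat template rescaled so each beat's maximum/minimum
equal the commanded SBP/DBP. White noise, respiratory baseline wander and a
configurable fraction of corrupted beats exercise the SQI gate.

The two-Gaussian model was chosen over hemodynamic simulators because it is
analytically differentiable — every fiducial point has a closed-form
dense-grid oracle, which the test suite exploits. What the generator does
**not** emulate: real PPG harmonic structure (dicrotic notch sharpness,
skin-perfusion nonstationarity), motion artifacts, sensor-specific transfer
functions, drug pharmacokinetics, or any physiologic coupling beyond the
planted link. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers a known morphology–BP relationship under realistic noise,
gating and inter-subject variability — not clinical accuracy on real
patients.

## Numerical choices

* Zero-phase filtering uses odd-reflection padding (2/hp_cut seconds) to
  suppress forward-backward edge transients of the 0.5 Hz high-pass.
* Integrals use the trapezoidal rule on the L-sample pulse; SPTI + DPTI
  equals the total integral exactly because the split lies on a sample.
* Alignment uses FFT cross-correlation of band-passed, centered signals;
  ties resolve to the smaller lag via `which.max`.
* The systolic peak is the first local maximum reaching 75% of the pulse
  range (the reflected wave can rival the smoothed systolic peak in
  amplitude; the systolic wave always comes first).
* Relevance permutations draw sequentially from one seeded RNG stream,
  iterating features in column order with repetitions innermost, making
  reports bit-reproducible and independently recomputable.
* Ties in relevance ranking break lexicographically by feature name.
* Windows with any non-finite sample are invalid; heart rates outside
  [20, 250] bpm invalidate a window.
* All run-level randomness derives from a single seed through a fixed
  integer map, so every stage is independently reproducible.

## Problem sizes in the shipped checks

The test suite validates filter responses against the analytic cascaded
Butterworth magnitude at 10 probe frequencies; fiducial detection against
dense-grid analytic extrema over 50 random pulse shapes (noting that the
APG e-wave of this pulse family can be flat to within 0.1% of the APG range
around its maximum, where a position comparison at one-sample resolution is
not identifiable and amplitude equivalence is asserted instead); pairing
arithmetic over 100 random table sizes; split leakage over 20 seeded
splits; planted-feature rank recovery (20 planted among 80, five seeds);
and the full end-to-end pipeline on one default 40-subject cohort, where
calibration-mode Lasso must cut the flat-model test STDE by at least 40%
for SBP and 25% for DBP and calibration-mode models must beat their
calibration-free counterparts. `scripts/acceptance.R` reruns the end-to-end
pipeline at a caller-chosen seed and writes all headline quantities as
JSON.

## Known limitations

* The pipeline estimates BP from morphology alone; pulse-arrival-time or
  ECG-derived features are out of scope.
* Calibration and estimation windows must come from the same recording;
  cross-day calibration drift is not modeled.
* The generator's morphology–BP link is intentionally simple; relevance
  rankings on synthetic cohorts reflect that construction, not clinical
  feature importance.
* GPR is fitted on a subsample and with a single shared length-scale by
  default; automatic relevance determination tends to overfit at this data
  size.
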