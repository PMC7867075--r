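---
title: "Sleep staging from head-worn accelerometer ballistocardiography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from head-worn accelerometer BCG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polysomnography scores sleep into 30-second epochs labelled WAKE, REM,
LIGHT (non-REM N1–N2) and DEEP (non-REM N3) from EEG/EOG/EMG. `bcgsleep`
estimates those four states from a far cheaper signal: a single 3-axis
accelerometer fixed to the forehead and sampled at 200 Hz. Two kinds of
information are present in that signal. Gross head movements (turning
over, repositioning) concentrate around WAKE. Between movements, the
heart's ejection of blood shakes the head measurably — the
ballistocardiogram (BCG) — and its dominant deflection, the J wave, is a
per-beat fiducial analogous to the ECG R wave, so the J-J interval (JJI)
series carries heart-rate-variability information that differs across
sleep stages: parasympathetic (HF) drive rises from REM towards DEEP,
and REM carries visibly irregular beat-to-beat intervals.

## Pipeline

Both feature branches first fuse the three axes into one nonnegative
envelope by the per-sample RMS, `sqrt((ax^2+ay^2+az^2)/3)`, which is
invariant under any fixed orthonormal rotation of the sensor — mounting
orientation and sleep posture therefore do not matter.

* **Movement branch**: 0.1 Hz high-pass (removes DC/gravity and drift),
  RMS fusion, then per 30-s epoch the mean (**AGM**, m/s²), population
  variance (**VGM**, (m/s²)²) and the total one-sided amplitude spectrum
  of the mean-removed epoch (**FS**). Mean removal keeps FS from
  duplicating AGM; the amplitude sum is scaled by the bin width (1/30 Hz).
  The scaling of FS is the one genuinely ambiguous unit choice in the
  design; it is exposed in the configuration (`features$fs_scale`) and
  affects nothing downstream because the second-step classifier sees only
  the per-recording z-score of FS.
* **BCG branch**: 1–10 Hz band-pass (suppresses drift and the ~0.25 Hz
  respiratory component, keeps the J-wave energy), RMS fusion, 0.325 s
  moving average (65 samples; one dominant envelope bump per beat), then
  J-peak detection and the 2 Hz JJI tachogram described below. Per epoch:
  tachogram mean (**AJJI**, s), population variance (**VJJI**, s²), and
  the band-power ratios **HF/TF** and **HF/LF** with
  LF = 0.04–0.15 Hz, HF = 0.15–0.4 Hz, TF their union, from the
  60-sample epoch DFT (resolution 1/30 Hz). Bins are assigned by center
  frequency with an inclusive-lower/exclusive-upper rule, so TF = HF + LF
  holds exactly by construction. VLF is deliberately not computed
  spectrally — a 2 Hz tachogram in 30-s windows has no usable resolution
  below 0.04 Hz — AJJI is its proxy.

### J-peak detection and correction

Local maxima of the smoothed envelope are detected with a minimum
separation of 0.365 s (the cardiac refractory period is about 0.2 s and
sleeping heart rates are comfortably below 160 bpm), keeping the taller
peak whenever two candidates conflict. Two corrections follow.

1. *Amplitude plausibility gate.* Candidates weaker than 30% of the
   local upper-decile peak amplitude (window of 31 peaks) are discarded.
   Between genuine heartbeats the envelope returns towards the noise
   floor, whose local maxima are typically an order of magnitude below
   the J-wave bumps; a relative gate removes them across recordings of
   very different absolute scale.
2. *Running-median interval rule.* Any inter-peak interval shorter than
   half the running 5-interval median marks a split beat; the weaker of
   its two bounding peaks is deleted and intervals are re-derived until
   stable. Deletion is deliberately restricted to *short* intervals:
   deleting a bounding peak can only merge intervals, so for
   over-detection it converges monotonically, whereas "repairing" a long
   interval (a missed beat, typically inside a movement burst) by
   deleting a peak would only widen the gap and, iterated, can consume
   the whole series. Missed-beat gaps are instead flagged on the
   tachogram (samples inside an observation gap longer than 3 s are
   marked `interpolated`) and handled by epoch-level imputation.

Intervals are timestamped at their later beat, resampled onto a uniform
2 Hz grid with a natural cubic spline (no extrapolation outside the
observed span; fewer than 4 points degenerate to a flagged constant
fill), and despiked with a 7 s running median (15 samples, odd by
construction, shrinking at the edges). The constant BCG-vs-ECG
conduction delay of 0.1–0.3 s is not corrected: it cancels in interval
differences.

Epochs with fewer than 30 usable tachogram samples get AJJI/VJJI (and
undefined band ratios) imputed with the recording median and are flagged
`jji_missing`; a fully beat-free recording falls back to a nominal 1 s
fill so the feature matrix stays finite.

## The two-step classifier

Step 1 labels every epoch WAKE or SLEEP from the five raw features
(AGM, VGM, FS, AJJI, VJJI): gross movement separates WAKE from SLEEP by
roughly an order of magnitude, so no standardization is needed or
wanted. Step 2 classifies the SLEEP epochs into REM/LIGHT/DEEP from

* the same five features z-scored *per recording over SLEEP epochs
  only* (WAKE epochs carry movement energy that would otherwise make the
  standardization depend on how much WAKE a night contains), plus the
  equally z-scored HF/TF and HF/LF — the S-prefixed names (SAGM …
  SHF/LF);
* **SET**, minutes since the first SLEEP-labelled epoch
  (`0.5 * (k - k_onset)`): DEEP concentrates early in the night and REM
  late, so elapsed sleep time is strongly informative;
* **HRT**, minutes since the last "head event" — an epoch with AGM above
  `median + 3*MAD` of the recording's SLEEP-epoch AGM, or a WAKE epoch,
  whichever is later — capturing the decline in head movement that
  precedes DEEP sleep by roughly ten minutes. The definition of HRT is
  the least constrained design point in the method; this movement-reset
  reading is one defensible choice and is isolated behind
  `head_rest_time()` with an explicit threshold argument.

Both steps use a random forest. The printed hyperparameter grid is split
criterion ∈ {gini, entropy}, depth 1–10, trees 1–10 (200 candidates per
step). No installed R forest exposes the entropy criterion, so the
forest is a thin bagging ensemble over `rpart` trees (which provide both
"gini" and "information" splitting) with a per-tree random feature
subspace of size `floor(sqrt(p))`; remaining tree controls are the
common learner defaults (minsplit 2, minbucket 1, cp 0). Per-tree seeds
derive from the forest seed, which has a useful side effect: the first
*k* trees of a 10-tree forest *are* the *k*-tree forest, so the
trees-axis of the grid search reuses one fit per (criterion, depth)
while still scoring all 200 candidates.

Hyperparameters are selected by leave-one-subject-out cross-validation
*inside the training pool* (nested selection), maximizing the macro
F-score; ties break toward smaller depth, then fewer trees, then gini.
Running the selection on all subjects including the test subject — the
procedure as usually printed — leaks the test subject into the choice;
it remains available as `paper_faithful = TRUE` in `loso_evaluate()`,
but the honest nested variant is the default. Step-2 candidates are
scored on truth-conditioned second-step features (standardization, SET
and HRT derived from the reference labels), matching how step-2 training
data are built; at inference the same features are rebuilt from the
step-1 *predictions*, which is the only conditioning available then.
Class weighting and resampling are deliberately absent: LIGHT dominance
and the resulting LIGHT-heavy error structure are properties of the
domain the evaluation should show, not hide.

Predictions merge as: WAKE exactly where step 1 said WAKE; otherwise the
step-2 label. Per-class scores are `p(WAKE)` and
`(1 - p(WAKE)) * p2(class)` (uniform over the sleep classes for
WAKE-predicted epochs), giving rows that sum to 1 and support
one-vs-rest ROC analysis on all four classes.

## Evaluation

Folds are subjects; both nights of the held-out subject are the test
set. The report carries per-fold per-class precision/recall/F and
accuracy, the pooled 4×4 confusion matrix with *estimation on rows and
correct labels on columns*, fold-averaged one-vs-rest AUCs (computed
with pROC), and ROC curves vertically averaged on a fixed 101-point
false-positive-rate grid. Feature significance follows the two-step
structure: paired Wilcoxon signed-rank for WAKE vs SLEEP on 20 randomly
drawn epochs per class for the step-1 features, and Friedman across
REM/LIGHT/DEEP followed (when significant at 5%) by pairwise Wilcoxon
with Bonferroni ×3 for the step-2 features. Summary statistics of
per-subject tables use the arithmetic mean and the *population* SD
(divisor n) — the convention under which every mean/SD/%Rate cell of the
bundled reference tables reproduces exactly — with rounding applied only
at report rendering.

## The synthetic generator

No public recording with reference hypnograms exists for this sensor
placement, so the package ships a seeded generator that embodies the
statistical structure the method relies on, making the whole pipeline
testable end to end:

* a semi-Markov hypnogram (gamma dwell times, shape 2; mean dwells WAKE
  1.5, REM 7, LIGHT 12, DEEP 9 min; exponential sleep latency, mean
  10 min) whose LIGHT-exit weights are time-modulated so DEEP falls and
  REM rises across the night;
* stage-dependent RR dynamics
  `RR(t) = mean + HF sin(2π·0.25t) + LF sin(2π·0.1t + φ) + jitter`,
  clipped at 0.4 s, with stage means 0.90/1.00/1.10/1.15 s
  (WAKE/REM/LIGHT/DEEP), HF amplitude rising towards DEEP, LF amplitude
  rising towards REM, and REM carrying the largest jitter;
* a damped-sinusoid BCG template (7 Hz center, 0.15 s decay, 0.35 m/s²
  peak, ±20% per-beat amplitude jitter — head BCG stays within about
  0.98 m/s², and published overnight feature magnitudes for this sensor
  placement guided the overall scale calibration) convolved with the
  beat impulse train on the vertical axis;
* a 0.25 Hz respiration sinusoid, white sensor noise (SD 0.02 m/s²),
  gravity on the vertical axis, an optional fixed rotation, and
  Poisson-placed gross-movement bursts (band-limited 0.5–8 Hz noise,
  2 m/s², 2–5 s, rates 1.2/0.08/0.05/0.01 per minute in
  WAKE/REM/LIGHT/DEEP).

Everything derives from the config seed through fixed sub-streams, so a
config reproduces its recording bit for bit, and each generator stage is
reproducible standalone.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: posture changes that re-orient the
sensor mid-night, apnea and other breathing pathologies, the full
I-J-K BCG morphology (only the envelope inside 1–10 Hz matters to the
method), non-stationary electrode/skin artefacts, inter-subject
anatomical variation in BCG amplitude, and scorer disagreement in the
reference hypnogram. Classifier accuracies on this generator are
accordingly optimistic relative to human recordings, whose published
four-class accuracy for this method sits near 75%; the synthetic gates
(LOSO accuracy ≥ 0.70, one-vs-rest AUC ≥ 0.80) are artifact-defined
checks that the pipeline recovers structure it is built for, not
reproduction targets.

## Numerical choices

* Filters are 4th-order Butterworth applied forward-backward: zero phase
  distortion, so peak times stay aligned with the epoch grid. At a
  normalized cutoff of 5×10⁻⁴ (0.1 Hz at 200 Hz) the transfer-function
  coefficients are poorly conditioned and leave a ~4×10⁻³ DC residual;
  subtracting the per-axis mean before filtering makes DC rejection
  exact without touching the passband. The filter passes run through
  C-level `stats::filter` (FIR by convolution, IIR recursively), which
  keeps an 8-hour, three-axis recording under a few seconds per filter.
  The same near-unit pole radius bounds how exactly linearity can hold in
  double precision: rounding is amplified by roughly the reciprocal
  distance of the poles from the unit circle, so the filters are linear
  to about 10⁻⁶ relative, not machine epsilon.
* Moving-average and median kernels are forced odd for symmetric
  centered windows; edge windows shrink to the available samples.
* The tachogram spline uses natural boundary conditions (no boundary
  derivative information exists) and never extrapolates.
* Population variance (divisor n) is used everywhere a variance or SD is
  a *feature or summary*, for internal consistency with the reference
  tables; `stats::sd` (n−1) appears only in the across-fold dispersion
  of the evaluation report.
* Degenerate inputs have defined outcomes rather than errors wherever a
  pipeline must keep running: constant-feature standardization yields 0
  with a warning, a beat-free recording yields nominal tachogram fills,
  an all-WAKE step 1 skips step 2, fewer than 4 spline points yield a
  flagged constant fill.
* Forest probability ties resolve to the first class level;
  grid-search ties to the simplest model. Both make predictions
  bit-stable under a fixed seed.
* The random-label control in the acceptance gates refits the per-fold
  chosen hyperparameters on permuted training labels; such a model
  collapses to the majority class, so its accuracy is compared against
  the majority-class prior of the pooled truth labels.

## Problem sizes

The acceptance-level checks run the generator at its default conditions:
one 8-hour night for beat-interval recovery (≈27,000 beats) and five
subjects × two nights (9,600 epochs) for the full leave-one-subject-out
gate; unit tests use minutes-long signals and small synthetic feature
tables. These sizes are the package's chosen test conditions and are
stated here so they can be scaled deliberately rather than accidentally.

## Known limitations

* The HRT definition is a reading of an under-specified feature; other
  definitions (e.g. purely WAKE-reset) plug in through the exposed
  threshold policy.
* The amplitude gate in peak detection assumes the J-wave envelope
  dominates the inter-beat floor by a sizable factor; very low BCG SNR
  (loose sensor contact) degrades to quality-flagged gaps rather than
  graceful partial detection.
* The step-2 training/inference asymmetry (truth- vs
  predicted-conditioned features) means step-1 errors propagate into
  step-2 feature quality at inference; this mirrors the two-step design
  rather than a removable implementation artifact.
* EDF ingest is not implemented; recordings arrive as CSV (`t, ax, ay,
  az` in SI units).
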