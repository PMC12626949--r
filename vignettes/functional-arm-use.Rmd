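---
title: "Classifying functional arm use from wrist accelerometry"
author: "armetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional arm use from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armetry)
```

## The problem

After a stroke, how much a person actually *uses* their affected (paretic)
arm in daily life is a key rehabilitation outcome, and it is poorly captured
by clinic-based capacity tests. Wrist-worn accelerometers record arm motion
continuously, but raw activity counts cannot distinguish *functional* use
(reaching, grasping, manipulating objects) from *non-functional* motion (arm
swing during walking, whole-body movement, stillness). `armetry` implements a
complete pipeline that learns this distinction from raw tri-axial wrist
accelerometry: per-frame video annotations are transferred onto the sensor
timeline, the signal is cut into 2-second windows, and a compact
convolutional network classifies each window as functional or
non-functional.

The package is testable end to end without any recorded data: a synthetic
cohort generator produces labeled multi-rate accelerometry with the
statistical structure the pipeline assumes.

## Pipeline

1. **Synchronization.** Before being strapped on, each sensor is oscillated
   rapidly along its z axis; the five reversal extrema of that oscillation
   are sharp peaks in the z signal. `detectSyncPeaks()` finds them (local
   maxima of `|z - median(z)|` above half the prelude maximum, at least
   0.1 s apart) and `alignClocks()` fits the least-squares linear map
   `t_sensor = offset + scale * t_video` to the matched sensor/video peak
   times. A linear (offset + drift) model rather than a pure offset is used
   because consumer sensor clocks drift. Two numerical safeguards matter
   here: peak times are refined to sub-sample precision by parabolic
   interpolation, and a fitted drift larger than `maxDrift` (default 0.5%)
   is treated as quantization noise and clamped to the offset-only map —
   the five peaks span only about a second, so an unconstrained slope
   through them can extrapolate to several seconds of misalignment by the
   end of a session.
2. **Down-sampling.** All traces are brought to 30 Hz
   (`resampleTo30Hz()`): a 4th-order Butterworth low-pass at 12 Hz (safely
   below the 15 Hz output Nyquist) applied forward-backward for zero phase,
   then linear interpolation onto the uniform 30 Hz grid. Gravity is *not*
   removed: the orientation information it carries is a strong cue for
   functional posture.
3. **Axis harmonization.** Left- and right-worn sensors see mirrored
   anatomy; `harmonizeAxes()` negates one configurable axis (default `x`) on
   left-side traces. The axis is configurable because the correct choice
   depends on the mounting convention of the hardware.
4. **Labels.** Three independent annotators label each video frame
   functional / non-functional / unknown per limb. `consensusLabels()` takes
   the strict per-frame majority (no majority → unknown), and
   `transferLabels()` moves the consensus onto the 30 Hz sensor timeline
   through the fitted clock map. Unknown frames mark data the annotators
   could not resolve; they are removed before modeling.
5. **Windowing.** `segmentAndWindow()` removes unknown samples, splits the
   remainder into maximal contiguous runs, and tiles each run with
   non-overlapping 60-sample (2 s) windows from its start, dropping trailing
   remainders. A window's label is the strict majority of its sample labels;
   tied windows are dropped (ties are rare, < 2% on synthetic cohorts). The
   choice of majority labeling is a design decision — the alternatives
   (center-sample labeling, excluding mixed windows) are defensible, but
   majority is the least surprising and keeps burst edges in the data.
6. **Variants.** Three dataset organizations (`assembleVariant()`): paretic
   channels + paretic labels; non-paretic channels + labels; and a combined
   6-channel variant `(x1, y1, z1, x2, y2, z2)` under paretic labels, where
   samples unknown on *either* arm are removed first — hence the combined
   variant never has more windows than the paretic one.
7. **Scaling.** A robust per-channel scaler (`fitScaler()`):
   `X_scaled = (X - Q2) / IQR` with the median and interquartile range
   pooled over all training windows and time steps. The scaler is fitted on
   the training split of each fold only and applied to both splits —
   fitting it globally would leak validation data into training.

## The classifier

`buildArchitecture()` describes a fixed two-stage network for 60 × C × 1
inputs (C = 3 or 6):

* feature extraction: two Conv2D blocks — 16 then 32 filters, 3 × 3
  kernels, each followed by batch normalization, ReLU and 20% dropout;
* aggregation/classification: flatten, two dense layers of 64 ReLU units
  with L2 weight decay (λ = 1e-3) and 30% dropout, and a single sigmoid
  unit giving P(functional).

Convolutions use "same" padding on both axes: with only 3 channel columns,
"valid" 3 × 3 convolutions would collapse the channel axis below one column
by the second block, and "same" keeps the 3- and 6-channel variants
shape-compatible. There are no pooling layers. For the 3-channel input the
network has 377,825 trainable parameters (`countParameters()` gives the
layer-by-layer arithmetic, verified in the tests against the actual weight
tensors).

Training (`trainModel()`, schedule in `trainConfig()`): Adam at 1e-3,
binary cross-entropy, batch size 64, up to 700 epochs. Two callbacks run
each epoch on the held-out fold: the learning rate is multiplied by 0.1
when the validation loss has not improved by more than 1e-4 for 10
consecutive epochs, and training stops once validation *accuracy* has not
improved for 20 epochs, restoring the best weights seen. Monitoring loss
for the plateau rule but accuracy for early stopping is deliberate: the two
callbacks are specified on different quantities.

The numerical engine is compiled (single-precision im2col convolutions on
BLAS, batch-norm epsilon 1e-3, running-statistic momentum 0.99, Adam
epsilon 1e-7). Weight initialization and minibatch shuffling draw from R's
RNG, and each epoch's dropout masks come from a fast counter-based stream
seeded from R's RNG, so a fixed seed reproduces a training run exactly on a
given machine. Dropout and batch statistics are frozen at inference:
`predictProba()` is deterministic for fixed weights.

## Class imbalance

Severely impaired subjects use the paretic arm rarely (3–8% functional),
which starves the functional class. `rebalanceTrainingSet()` implements
SMOTE from scratch: each synthetic window is `x_i + u (x_nn - x_i)` with
`u ~ U(0, 1)` and `x_nn` one of the `k = 5` nearest minority neighbors in
flattened, scaled window space. With the default target ratio 0.5 the
minority class is brought to exactly half the majority count — a 33.3%
minority fraction. SMOTE runs *after* scaling (Euclidean distance is only
meaningful across channels on a common scale) and only ever on the training
split; synthesis provenance (parent, neighbor, interpolation coefficient)
is recorded so the geometry can be audited. Both orders (scale→SMOTE vs
SMOTE→scale) are defensible; the scaled order was fixed here for the
distance argument above.

## Evaluation

* **Intrasubject:** stratified 5-fold cross-validation within each subject
  (`makeIntrasubjectFolds()`); stratification prevents empty-functional
  folds for low-use subjects. Per-subject fold means are aggregated as
  mean ± SD across subjects.
* **Intersubject:** leave-one-subject-out (`makeLosoFolds()`); the held-out
  subject is the monitored validation set, and a leakage guard asserts on
  every fold that no subject appears on both sides.
* **Metrics:** accuracy and per-class F1 (`computeMetrics()`), functional
  as the positive class for the functional F1. An F1 whose class never
  occurs is reported as 0 with a warning — mirroring the near-zero
  functional F1s of severely impaired subjects rather than dropping them.
* **Train-vs-validation statistics:** `pairedComparison()` reports a
  two-sided paired t-test, and Cohen's d in two conventions (the pooled-SD
  paired d with a pairing-corrected CI, and `d_z = mean(diff)/sd(diff)`),
  because the convention behind published effect sizes of this kind is
  often unstated; neither is asserted as *the* original.
* **Baseline:** a random forest (500 trees) on a standard HAR time-domain
  feature set — per channel mean/SD/min/max/RMS, per arm signal magnitude
  area and magnitude mean/SD, and pairwise channel correlations (21
  features for one arm, 51 for two). `runBaseline()` reuses the *identical*
  fold manifests as the network so the comparison is split-for-split.

## The synthetic cohort generator

`generateSession()` emulates what the pipeline assumes about real wrist
data, without claiming biomechanical fidelity:

* a sync prelude — 2.5 cycles of a 2 Hz, 2 g z-axis oscillation (1.25 s),
  whose 5 alternating extrema are the reversal peaks, followed by a 0.75 s
  rest gap;
* rest carries +1 g on the configured gravity axis plus white noise;
* functional bursts are smooth minimum-jerk gravity re-orientations
  (40–80° tilt) with superimposed low-frequency movement pulses, placed to
  hit the profile's `functionalFraction` exactly up to rounding (burst
  count follows `burstRate` and `burstDurationS`, with the fraction
  binding);
* non-functional segments are stillness or ~1.9 Hz sinusoidal gait
  oscillation of amplitude `gaitAmplitudeG`;
* annotator disagreement is confined to label transitions: each annotator's
  perceived boundary shifts by up to `transitionJitterS`, sometimes leaving
  short unknown stretches — matching the observation that most human
  disagreement concerns transition timing. Ground truth itself contains no
  unknowns; unknown is an annotation artifact.

Each cohort subject gets a sampling rate drawn from {30, 50, 200} Hz, a
random paretic side, a sensor/video clock offset (video starts first) with
a small drift, and a *lower* functional fraction on the paretic side —
exercising the imbalance path the way real use-ratio data would.

What the generator does **not** model: soft-tissue artifact, validated
reach/grasp kinematics, activity-specific spectra (the spectral content of
functional vs non-functional movement is not characterized in the source
data, so these are free choices), sensor saturation or dropout. A pipeline
that passes on these cohorts is verified as *machinery* — preprocessing
arithmetic, protocol fidelity, leakage hygiene, learnability of a cleanly
separable signal — not as a clinical claim about real stroke data.

## Study-scale checks and problem sizes

The package's property checks run the full pipeline at desk scale, chosen
once as realistic for the conditions they probe:

* a *homogeneous* separable cohort — 8 subjects, 10 minutes each, sensor
  noise 0.02 g — for intrasubject (5-fold) and leave-one-subject-out
  accuracy;
* a *heterogeneous* cohort — 4 subjects, 4 minutes, with gravity axis,
  noise (0.02–0.12 g), functional fraction (0.1–0.5) and gait amplitude
  varied per subject — where the intrasubject-minus-LOSO accuracy gap
  should be positive, since a left-out subject's orientation and noise
  regime are unseen at training time;
* an *imbalance stress* cohort — three balanced subjects (40% functional)
  and one at 5%, with short fragmented bursts (2 s at 8/min), modest
  gravity tilt (15–35°) and noise 0.25 g. The weak signal is the point: at
  the default tilt and noise the classes are so separable that a handful of
  minority windows suffice and imbalance is harmless; in the weak-signal
  regime the low-use subject's functional F1 drops well below the balanced
  subjects' while accuracy stays high (the imbalance signature), and SMOTE
  at ratio 0.5 must not make it worse.

## Numerical choices and degenerate inputs

* Quantiles use R's default type-7 definition; the scaler's IQR of a
  constant channel is replaced by 1 with a warning (output all zeros).
* A sample lying exactly on a video-frame boundary is snapped to the later
  frame (a 1e-6-frame guard against floating-point roundoff).
* Tied windows (equal functional and non-functional sample counts) are
  dropped, not guessed.
* `smoteSynthesize()` refuses minority sets no larger than `k`;
  `trainModel()` refuses single-class training data and points the caller
  at rebalancing.
* Sync detection is invariant to a constant z offset (gravity) because the
  prelude median is subtracted first; a flat trace reports 0 peaks found.

## Limitations

The classifier and protocol are faithful to their specification, but all
quantitative results in this package are on synthetic cohorts; accuracy on
real stroke accelerometry depends on signal structure the generator does
not attempt to reproduce. Datasets persist as plain CSV/YAML rather than a
binary container, which is adequate at desk scale but slow for very large
cohorts. The left/right harmonization axis and the window-labeling rule are
configurable design decisions, not published facts.
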