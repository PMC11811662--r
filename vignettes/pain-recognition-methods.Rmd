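---
title: "Methods: multimodal physiological pain recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal physiological pain recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Postoperative patients report pain sparsely — a numerical rating scale (NRS)
score of 0–10, given only now and then while performing light physical
activities — yet their physiology carries continuous information about pain:
heart rate rises and beat-to-beat variability falls, facial muscles produce
EMG bursts, skin conductance responses (SCRs) become more frequent, and
breathing quickens. `painpipe` implements a complete recognition pipeline
from raw multimodal biosignals (ECG and 5-channel facial EMG at 500 Hz from a
biopotential device; electrodermal activity at 4 Hz and photoplethysmography
at 64 Hz from a wristband) to leave-one-subject-out (LOSO) balanced-accuracy
estimates for binary tasks that contrast a no-pain baseline (`BL`) against
three pain intensities (`PL1` < `PL2` < `PL3`, obtained by downsampling NRS:
1–3, 4–6, 7–10; NRS 0 maps to `BL` by default so the binary tasks have
disjoint classes — a `strict_ranges` flag restores the literal 0–3 range for
`PL1`).

Because no public patient dataset accompanies this problem, the package
ships a synthetic cohort generator with known ground truth; every stage of
the pipeline is tested against that ground truth, and the acceptance
properties state their assumptions through the generator's parameters.

## Preprocessing

Each modality gets its own cleaning chain, all filters Butterworth and all
applied zero-phase (forward–backward), since downstream features are
morphology- and timing-based and must not be phase-shifted:

* **ECG** — band-pass 0.1 Hz to `min(250, 0.45 fs)` Hz. The nominal upper
  edge of 250 Hz collides with the Nyquist frequency at `fs = 500`, so it is
  clamped to 225 Hz, preserving the intent while keeping the filter stable.
  Band-passes are realized as a high-pass/low-pass cascade of the same
  order: a direct transfer-function band-pass spanning 0.1–225 Hz at 500 Hz
  is numerically fragile, while the cascade is stable and meets the same
  response contracts.
* **EMG** — 20 Hz high-pass, then notch filters (biquad, Q = 30) at 50 Hz
  and 100 Hz against powerline interference and its harmonic.
* **EDA** — 1 s centered moving average against motion artifacts, then a
  1 Hz low-pass.
* **PPG** — band-pass 0.4–8 Hz (covering cardiac activity and its
  respiratory modulation sidebands), then a short moving-average smoother.

Filter order defaults to 4 and is configurable; forward–backward filtering
uses odd-reflection end padding, which suppresses the start/end transients
that plain filtering would inject into the first tens of seconds.

## Handcrafted features

Features are computed on non-overlapping windows of 5.5 or 10 s (the window
step is configurable; non-overlap is the default because overlap would leak
information between neighboring labeled instances).

* **ECG (19)** — R-peaks come from a deterministic Pan–Tompkins-style
  detector (QRS band-pass, derivative, squaring, 150 ms integration,
  adaptive threshold, 200 ms refractory period, apex refinement). A learned
  detector can be substituted behind the same interface; the deterministic
  default keeps results reproducible and testable. From the NN intervals in
  each window: least-squares slope, count, mean, min, max, SD; signed
  successive-difference mean/min/max, SDSD, RMSSD, NN20, NN50, pNN20,
  pNN50; and mean/min/max/SD of per-interval heart rate (60000/NN ms).
  Windows with fewer than 3 intervals yield a missing sentinel and are
  dropped from the feature matrix.
* **EMG (14 × 5 = 70)** — per channel: peak |amplitude|, mean peak-to-peak
  over 0.5 s sub-frames (the name "peak-to-peak mean" does not pin down a
  definition; sub-frame max−min is the interpretation here, with the frame
  length configurable), RMS, mean |second differences|, mean |first differences|,
  both again on the z-scored window, means of local minima and maxima
  (strict neighbor comparison; plateaus take their first sample; constant
  windows fall back to the constant), mean |x|, variance, SD, range, IQR.
* **EDA (12)** — the cleaned signal is decomposed into tonic + phasic +
  residual (below); features are the SCR count on the phasic component
  (topographic prominence ≥ 0.01 µS) plus mean, max, min, range, SD, IQR,
  RMS, local-extrema means and mean |first/second differences| of the clean
  window.
* **Respiration (10)** — from the PPG-derived respiratory signal (below):
  inhale-peak count (prominence ≥ 20 % of the window range, spacing ≥
  1.5 s — scale-free thresholds, chosen because nothing about the method
  fixes an absolute amplitude scale), mean, max, min, range, SD,
  inhale-interval mean/SD/RMSSD, and SD
  of inhale duration (preceding trough to peak).

### EDA phasic decomposition

The decomposition follows the cvxEDA model: the phasic component is a
sparse, nonnegative sudomotor driver convolved with a Bateman impulse
response `exp(-t/τ1) − exp(-t/τ0)` (defaults τ0 = 0.7 s, τ1 = 2.0 s, the
published constants of that model), and the tonic component is a smooth
cubic B-spline (10 s knot spacing; the basis spans constants and linear
drift). The driver solves a nonnegative lasso,

$$\min_{u \ge 0,\, c} \tfrac12\lVert y - Ku - Bc\rVert^2 + \lambda \sum_i u_i,$$

by FISTA with a nonnegative soft-threshold step (λ = 0.05 µS by default,
300 iterations), re-projecting the spline coefficients each iteration.
Nonnegativity of the impulse response and driver makes the phasic component
nonnegative elementwise, and tonic + phasic + residual reconstructs the
input exactly by construction. Smoothing and low-pass filtering happen
before decomposition.

### Respiration from PPG

After the 0.4–8 Hz band-pass, any additive baseline respiratory component
is gone; respiration survives in the PPG as *amplitude modulation* of the
cardiac pulse. Plain empirical mode decomposition (EMD) of an
amplitude-modulated carrier cannot isolate the modulator — the upper and
lower envelopes are symmetric, so the whole signal sifts out as one
intrinsic mode function. The package therefore first demodulates: a cubic
spline through the systolic peaks forms the beat-amplitude envelope, EMD
(classic sifting with spline envelopes and a Cauchy stopping criterion)
decomposes that envelope, and the respiratory signal is the sum of the IMFs
whose dominant FFT frequency lies in 0.1–0.5 Hz (6–30 breaths/min). If no
IMF lands in the band, or the candidate carries less than 2 % of the PPG's
amplitude, the signal has no respiratory component and the pipeline says so
rather than inventing one.

## Automatic features

Two autoencoder families learn per-modality latent features, trained to
minimize reconstruction MSE with Adam (learning rate 1e-3, batch size 10,
100 epochs), fully seeded:

* **CNN** — dense layer onto an internal grid of CP2 samples (the power of
  two closest to the input length, ties broken downward), three strided
  1-D convolutions (kernel 3, stride 2, channels 16/32/64, fixed here as
  documented defaults), dense to the latent
  vector; the decoder mirrors with three transposed convolutions. ReLU
  between layers; latent and output layers linear.
* **LSTM** — the window is average-pooled to CP2/8 steps, a single-layer
  LSTM (hidden 64) reads it, the last hidden state projects to the latent
  vector; the decoder LSTM receives the latent at every step and projects
  back. This is the smallest architecture satisfying the shape contract.

Latent sizes: 32 for ECG, EDA and respiration; 6 per EMG channel (one
autoencoder per channel, 30 over the montage) — 126 features across the
four modalities. Windows are min–max normalized per window (z-score
available), and are linearly resampled to fixed per-modality lengths before
encoding (defaults: ECG/EMG 512, EDA 64, RR 128 samples). Resampling is
needed because at native wristband rates a 10 s EDA window has 40 samples,
whose nearest power of two (32) cannot hold a 32-dimensional latent, and it
keeps single-CPU training tractable. Both forward and backward passes are
hand-written array code verified against numerical gradients in the test
suite.

Autoencoders are trained only on training-fold subjects during evaluation:
training them on held-out subjects would leak subject-specific structure
into the features, so the leakage-free choice is the default and the
stricter protocol.

## Labels, weak supervision, oversampling

A window is **strongly labeled** when its midpoint lies within the labeling
threshold (the window length: 5.5 or 10 s) of an NRS report; windows fully
inside designated rest spans are `BL`. Two equidistant, conflicting reports
discard the window. Midpoint matching is one of three defensible
conventions (start/midpoint/end); midpoint is symmetric and is used
throughout.

**Weak supervision** labels the remaining windows with a three-member label
model — RBF-kernel SVM (Platt-calibrated probabilities), random forest, and
uniform-weight 5-NN — trained on the strong set; each unlabeled window
receives the class whose maximum calibrated probability across members is
largest, ties broken by the fixed member priority SVM > RF > KNN. This
implements the most-confident-prediction rule directly rather than a
generative label-model fit. Weak labeling is skipped
when the strong set has fewer than 2 classes or fewer than 10 instances in
any class. Evaluation sets only ever contain strong labels.

**SMOTE** equalizes training-class counts by sampling a minority instance,
one of its k = 5 nearest minority neighbors (Euclidean distance after
per-feature standardization fit on the training fold), and a uniform point
on the segment between them. It runs inside training folds only, after
feature selection (so synthesis happens in the 25-feature space).

## Models, fusion, evaluation

Feature selection keeps the top 25 columns by random-forest Gini
importance, fit on the training fold. Classifiers: RBF SVM (C = 1,
γ = 1/p on standardized features), random forest (100 trees), AdaBoost
(SAMME over 50 depth-1 stumps), and 5-NN (standardized features); trees
consume raw features. Hyperparameters are library defaults with fixed
seeds; they are conventional choices, documented rather than tuned.

**Early fusion** concatenates per-modality feature vectors for windows
whose midpoints agree within the window length, in fixed modality order
ECG, EMG, EDA, RR. **Late fusion** trains one classifier per modality and
majority-votes, breaking ties by mean confidence and then by modality
order.

Evaluation is leave-one-subject-out: all fitting — weak labels, selection,
SMOTE, standardization, classifier, and autoencoder training — happens on
the training subjects; the held-out subject contributes only strong labels.
Folds whose held-out subject lacks one of the two task classes are excluded
from the mean/SD (scoring them 0.5 instead is available by flag). The
report gives per-fold confusion counts and balanced accuracy
`(TPR + TNR)/2`, with cross-fold mean and SD.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, not
the biophysics. Per subject: a session (default 600 s) of rest interleaved
with three activity segments (default 80 s) carrying one NRS band each
(1–3, 4–6, 7–10 in random order), with NRS reports only during activity
(every 20 s) — reproducing the sparse-label regime. Subject-level baselines
(resting heart rate 55–85 bpm, respiratory rate 12–16 breaths/min, tonic
EDA 2–10 µS) create the inter-subject variability that makes LOSO
meaningful. Effects per NRS point: +1.5 bpm heart rate, −5 % SDNN, +0.4
SCRs/min, +0.5 breaths/min, and EMG bursts at 10 × 0.15 × NRS times the
noise floor (an NRS-0 segment has no bursts). ECG is built from template
P-QRS-T beats at AR(1) RR intervals; EDA SCRs arrive as a thinned Poisson
process with a 5 s refractory and full impulse responses inside the record
(so the injected count is well-defined ground truth); PPG is a cardiac
oscillation amplitude-modulated at the respiratory frequency.

Two generator choices matter for the validity of the acceptance
properties. Motion artifacts are injected *uniformly in time*, not
preferentially during activity: artifacts correlated with activity would
make baseline-versus-pain tasks classifiable even with all pain effects set
to zero, destroying the null-calibration property by construction. And all
effect couplings scale to exactly zero with their effect sizes, so the
zero-effect cohort is a true null.

What the generator does **not** emulate: realistic ECG morphology
variation, ectopic beats, electrode pops, EDA storms, respiratory sinus
arrhythmia beyond the modeled couplings, or any patient-specific pain
semantics. Passing tests therefore demonstrate that the pipeline recovers
structure it was designed to recover under its stated assumptions — not
clinical performance on real patients.

## Problem sizes and numerical choices

The test and acceptance runs use 300 s sessions, cohorts of 6 (null
calibration, 20 replicates, every task × classifier) and 8 subjects
(separability, 20 replicates), and autoencoders at reduced input lengths
and epochs where only shape contracts are under test. These sizes were
chosen to exercise every code path at single-CPU scale while keeping the
statistical checks adequately powered (null calibration is tested at ±3
standard errors over cohort replicates).

Ties and degenerate inputs: constant windows z-score to zero and take the
constant for local-extrema means; `closest_power_of_two` breaks ties
downward; equidistant conflicting annotations discard the window; weak
labeling and SMOTE degrade with explicit warnings (skip, or reduced k)
rather than failing silently; the EDA optimizer's additivity is exact by
construction, so a failed fit is detectable as a large residual rather than
a broken identity.

## Known limitations

* Balanced accuracies on synthetic cohorts say nothing quantitative about
  patient data; clinical performance claims require a patient dataset,
  which this package does not ship.
* The LSTM autoencoder architecture is a deliberately minimal design for
  a genuinely open choice.
* The respiration path assumes amplitude modulation is the dominant
  respiratory imprint on wrist PPG; strong additive baseline respiration
  below 0.4 Hz is discarded by the band-pass.
* Single-CPU training: the autoencoders are small by deep-learning
  standards, which is sufficient for the latent-size contracts but not for
  representation-learning claims.
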