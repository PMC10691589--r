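---
title: "Staging running fatigue from wearable IMU windows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging running fatigue from wearable IMU windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runfatigue)
```

## The problem

A runner's gait changes as fatigue accumulates: foot-strike impacts are
attenuated, limb swing grows, posture drifts forward, and cycle-to-cycle
variability increases. `runfatigue` classifies one-second windows of raw
9-axis inertial data (tri-axial accelerometer, gyroscope, magnetometer at
200 Hz, worn at the shank, thigh or pelvis) into three fatigue stages —
`Pre`, `Mid`, `Post` — without segmenting gait cycles. The pipeline is:
simulate or load recordings, low-pass filter the accelerometer and
gyroscope, optionally estimate the 3-D attitude (Euler angles) by Kalman
fusion, cut constant-length windows with configurable overlap, shuffle
and split 72/18/10, and train one of five deep classifiers.

## The synthetic cohort

Real multi-runner recordings of this kind are rarely shared, so the
package ships a generator that emulates the study conditions and makes
every downstream stage testable. Each subject gets a stride frequency
(`N(1.4, 0.1)` Hz), a vertical impact amplitude (`N(3, 0.5)` g) and a
peak swing rate (`N(200, 30)` deg/s). Per gait cycle the generator
places a Gaussian impact transient on the vertical accelerometer axis, a
positive sagittal swing lobe balanced by a counter-rotation lobe on the
gyroscope (so pitch stays bounded), and sinusoidal lateral components;
the magnetometer observes a fixed world field rotated by the simulated
orientation, which is obtained by exactly integrating the body angular
rates and kept as ground truth on the recording.

Fatigue stages act as multiplicative effects, attenuated per sensor site
(shank 1.0, thigh 0.6, pelvis 0.35):

| stage | impact | swing | forward lean | variability |
|-------|--------|-------|--------------|-------------|
| Pre   | 1.00   | 1.00  | 0 deg        | 1.0         |
| Mid   | 0.90   | 1.15  | 3 deg        | 1.1         |
| Post  | 0.80   | 1.30  | 6 deg        | 1.2         |

The directions follow the impact-attenuation account of fatigued
running (softer distal loading, larger swing); the magnitudes are
package conventions, configurable per `stage_effect()`, and deliberately
produce windows a linear classifier can separate — a floor that the
test suite verifies with `nnet::multinom` on per-window RMS features.
Per-stage RPE (6.6/11.9/15.2 on the Borg 6-20 scale) and heart rate
(163.2/171.8/178.0 bpm) are drawn as stage metadata. What the generator
does **not** emulate: ground-reaction mechanics, sensor dropout,
soft-tissue artefacts, inter-day drift, or asymmetry. Passing tests on
this cohort demonstrate that the pipeline and models work as specified;
they are not evidence about any real cohort.

The default cohort used by the end-to-end checks is 6 subjects, shank
site, 20 s per stage — about 700 windows at 50% overlap. These sizes
are the package's own choice of demonstration scale.

## Signal conditioning

Accelerometer and gyroscope channels are low-pass filtered with a
fourth-order Butterworth at 15 Hz (fs 200 Hz). The digital filter is an
impulse-invariant realization of the analog prototype (partial fractions
over the left-half-plane poles, numerator renormalized to exact unit DC
gain), so the single-pass magnitude follows
$|H(f)| = 1/\sqrt{1 + (f/f_c)^{2n}}$ across the band; a bilinear design
would over-attenuate near Nyquist by frequency warping. The default is a
single causal pass — matching deployable real-time use and the −3 dB
property at the cut-off — with `zero_phase = TRUE` available for
forward–backward filtering.

Orientation is estimated by a quaternion error-state Kalman filter: the
gyroscope propagates the attitude; gravity (accelerometer) corrects roll
and pitch; the magnetometer corrects yaw against a world-field reference.
Two choices matter under running dynamics, where periodic linear
accelerations corrupt the measured gravity direction even when the
specific-force norm is near 1 g:

* **Moving-base coarse alignment.** The first 2 s of accelerometer and
  magnetometer samples are rotated into the frame of sample 1 via the
  integrated gyroscope and averaged; periodic linear accelerations
  largely cancel over whole gait cycles, leaving clean gravity and field
  directions for initialization. Yaw is reported relative to the
  starting heading.
* **Smoothed innovations.** Corrections are driven by innovation vectors
  low-passed over about one gait cycle (`innovation_tau = 1` s), with a
  gate excluding samples far from 1 g (`acc_gate = 0.5` g), so the
  quasi-periodic corruption averages out instead of dragging the
  attitude.

Default noise parameters (process 0.3 deg/s, gravity-direction SD 0.25,
field-direction SD 0.4, initial attitude SD 10 deg) are filter-design
choices validated by the recovery properties: static attitudes within
1 deg, a 100-degree commanded yaw within 5 deg, and noise-free gait
within 3 deg RMS of the generator's ground truth. Euler angles use the
intrinsic Z-Y-X (yaw-pitch-roll) convention, reported in degrees and
wrapped to [−180, 180]. The attitude channels fed to models (`POS`) are
computed from the unfiltered 9-axis stream; filtering order is
configurable.

## Windows, labels and splits

The per-sample feature vector is `(ax, ay, az, gx, gy, gz, px, py, pz)`
or a prefix of it (`channel_combo`: ACC, GYR, ACC_GYR, ACC_GYR_POS).
Windows are `Nc = 200` samples (1 s — at least one full gait cycle,
which is why `subject_profile` requires stride frequency above 0.5 Hz,
enforcing `Nc >= fs * T`), cut per contiguous same-label segment at
steps of `round(Nc * (1 - overlap))` — 200 or 100 for the two study
overlaps — so windows never straddle a stage boundary, and each segment
of length `L` yields `floor((L - Nc)/step) + 1` windows. No
standardization is applied: models consume raw sensor units (a z-scoring
flag exists for experimentation only). Splitting shuffles pooled windows
by seed and takes `floor(0.10 N)` test, `floor(0.18 N)` validation,
remainder train (72/18/10). Pooled shuffling allows windows of the same
subject on both sides of a split; `by_subject = TRUE` provides the
leakage-free alternative at coarser proportions.

## The five classifiers

All models map a `200 x D` window to three softmax probabilities and are
declared as `model_spec` objects whose per-layer parameter formulas
(LSTM `4u(d+u+1)`; Conv2D `k_h k_w c_{in} c_{out} + c_{out}`; Dense
`d_{in} d_{out} (+ d_{out})`; BatchNorm `2u`) must equal the
instantiated network's trainable-weight count — the test suite asserts
the bridge for every architecture and input width.

* **S_LSTM** — LSTM(128, final state) → batch standardization →
  dropout 0.5 → dense softmax with L2 (0.01) on the head weights and
  output.
* **D_LSTM** — LSTM(128, sequences) → dropout → LSTM(64, final state) →
  batch standardization → dropout → the same head.
* **CNN** — Conv(32, 18×1, stride 2, same) → MaxPool(2×1) →
  Conv(64, 9×1) → Conv(128, 3×1) → MaxPool(2×1) → Conv(128, 1×D,
  valid) → Flatten → Dense(3). For D = 6 the flatten width is 3,200 and
  the total 151,843 parameters.
* **LSTM_ATTN** — LSTM(128, sequences) → dropout → the last hidden state
  becomes the query `q`; a bias-free 128×128 projection scores each
  step, scaled dot products `s_n = (W h_n)^\top q / \sqrt{u}` are
  softmax-normalized into the attention distribution, the context is the
  weighted sum of hidden states, and `[context, q]` passes through a
  bias-free 256×128 tanh projection before the head. The bias-free
  projections are forced by the published counts (16,384 = 128·128;
  32,768 = 256·128); tanh on the output projection is a package choice
  where the activation is unstated. Total for D = 9: 120,195.
* **LSTM_CNN** — the S_LSTM trunk (through batch standardization and
  dropout) and the CNN trunk (through flatten) read the identical input;
  their features concatenate (128 + 3,200 for D = 6) into a softmax
  head.

Batch standardization appears in the plain LSTM models but not in the
attention model, whose published layer table excludes it. The CNN uses
plain 2×1 max pooling throughout: the published layer table's shapes and
counts are only consistent with local pooling, so the table is followed
where the accompanying text suggests global pooling. The first
convolution halves the 200-step axis via stride 2 with same padding,
which matches the printed output shape without changing the parameter
count.

The loss is categorical cross-entropy, mean over samples of
$-\sum_k p_k \ln q_k$ with predictions clipped at $\varepsilon = 10^{-7}$
(the mean-over-samples convention resolves an ambiguity in whether the
normalizer counts samples or classes), plus the L2 penalties above.

## Training engine and regime

No deep-learning framework is available to this package's target
environment, so the architectures run on the package's own engine:
batched forward/backward passes written as BLAS matrix products, with
the LSTM cell recursion and convolution im2col/col2im in compiled code.
Correctness rests on central-difference gradient checks for all five
architectures on down-scaled variants (the builders accept reduced
`units` for exactly this purpose) and on the trivially verifiable layer
algebra tests. Initialization is Glorot-uniform (orthogonal recurrent
blocks, forget-gate bias 1); dropout is inverted; batch normalization
uses momentum 0.9 running statistics for inference.

The regime follows the study design: Adam, batch 256, at most 200
epochs, early stopping after 14 epochs without improvement of the
monitored loss (validation loss by default), restoring the best-epoch
weights — restoration is a package choice where the source regime is
silent, as is the monitored quantity. The learning rate is never stated
in the source regime; `train_control()` defaults to 1e-3. On raw-unit
windows the gyroscope channels are two orders of magnitude larger than
the accelerometer channels, which saturates the softmax at
initialization; at 1e-3 the CNN needs well over 30 epochs to escape,
so the end-to-end demonstrations configure 3e-3, which trains cleanly,
while 1e-2 destabilizes training. Class weighting is not used: the
synthetic cohort is balanced by construction.

The end-to-end checks train the CNN on the default cohort for at most 30
epochs (test accuracy at least 0.80) and compare the LSTM/CNN fusion
against the plain LSTM over ten seeded repeats, each fit on a reduced
200-window training subset for 8 epochs and scored on every window not
used for fitting or monitoring (~380 windows, so the evaluation noise
is well below the effect under test) — a deliberately small design
whose claim is only the ordering, not absolute accuracy.

## Degenerate inputs and numerical edges

Windows shorter than `Nc` are discarded (a fully short series yields an
empty window set with a warning, not an error); splits require at least
10 windows; a zero-norm accelerometer over the alignment window is a
degenerate-attitude error; filter cut-offs at or above Nyquist and
non-positive durations are invalid arguments. Softmax rows are computed
max-shifted; attention weights are strictly positive by construction;
sensor outputs are clipped to the instrument ranges (±16 g, ±500 deg/s).

## Known limitations

The engine is single-threaded and sized for demonstration cohorts, not
for the tens of thousands of windows a full study would produce. The
pooled-shuffle default leaks subject identity across splits exactly as
the source protocol describes; subject-level splitting is available and
recommended for any real generalization claim. The synthetic cohort's
effect sizes are conventions: accuracy on it says nothing quantitative
about real running data. Orientation estimation assumes a roughly
constant magnetic field and no hard/soft-iron calibration.
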