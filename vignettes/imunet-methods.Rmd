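---
title: "Methods: from raw sensor frames to activity labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw sensor frames to activity labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imunet)
```

imunet implements a complete human-activity-recognition (HAR) pipeline for
waist- or wrist-worn inertial measurement units (IMUs): decoding the
sensor's binary wire format, conditioning the signals, and classifying
fixed-length windows with a neural architecture that combines a
transformer encoder with a multi-scale convolutional branch, a
direction-aware axial-attention branch, and a learned gate that fuses the
two. This vignette explains each stage, its assumptions, and the design
choices that were genuinely open.

## 1. The sensor frame protocol

JY61-family IMU modules stream each sample as three consecutive 11-byte
frames — acceleration, angular velocity, attitude angle — each laid out as

```
0x55 | type | 8 payload bytes | checksum
```

with type bytes `0x51/0x52/0x53` and the checksum equal to the low byte of
the sum of the ten preceding bytes. Every physical value travels as a
little-endian signed short, converted by the range-based rule
`value = raw / 32768 * full_scale` with full scales of ±16 g, ±2000 °/s
and ±180°. Payload bytes 7–8 carry the chip temperature (`raw / 100` °C);
it is exposed but never fed to the classifier. Firmware aggregates ten
samples per transmission packet, so a 100 Hz sample stream becomes 10
packets per second.

Two datasheet figures deserve a note. The accelerometer's quoted
sensitivity (16,384 LSB/g) and the gyroscope's (131 LSB/°/s) are
register-level constants of the underlying MPU6050 and are *inconsistent*
with a ±16 g / ±2000 °/s 16-bit transmitted word; their reciprocals
(6.1×10⁻⁵ g, 7.6×10⁻³ °/s) are the resolutions a datasheet quotes. The
codec always uses the range-based rule; `sensor_resolution()` exposes both
conventions so either figure can be reproduced.

The parser is designed for dirty streams: it scans forward for a header
byte, validates the checksum, and counts — rather than raises on —
corruption. `encode_frame()` inverts the codec (quantizing
round-to-nearest, so round trips are exact to half an LSB per channel),
which is how the synthetic generator produces realistic binary streams.

## 2. Signal conditioning

The conditioning order is fixed: low-pass filter, then polynomial
smoothing, then windowing, then label filtering, then normalization.

**Butterworth low-pass (order 4, cutoff 2.5 Hz).** Human activity
concentrates its spectral power below roughly 3 Hz; a fourth-order
Butterworth low-pass at 2.5 Hz removes jitter and high-frequency
artifacts. The filter is applied forward and backward per axis so the net
phase shift is zero. Numerically, each pass is initialized at its
steady state for the first sample and the signal is extended by odd
reflection over `3 × (order + 1)` samples, so constants pass through
exactly. One further choice is ours: the package averages the
forward–backward and backward–forward pass orders. The two compositions
agree for an infinite signal but differ by edge transients on finite
ones; averaging makes time-reversal equivariance
(`filter(rev(x)) = rev(filter(x))`) exact in floating point rather than
approximate.

**Savitzky–Golay smoothing (window 11, order 3).** A local least-squares
cubic fit smooths residual noise while preserving peaks and inflection
points; by construction it reproduces any cubic signal exactly. Edges are
handled by evaluating the same local fit at edge offsets, so the
exactness property holds at the boundaries too.

**Windowing.** Signals are cut into windows of `T = 200` timesteps with a
stride of 100 (50 % overlap). Windows are 0-based and half-open; a
trailing remainder shorter than `T` is dropped. The sources the package
targets state two sampling regimes — 100 Hz hardware streams (2 s
windows) and 20 Hz benchmark processing (10 s windows) — so the sampling
rate is an explicit configuration field rather than a constant; the
synthetic defaults use 20 Hz.

**Label consistency.** Only windows whose timesteps all share one label
are kept: windows straddling an activity transition are ambiguous
training targets. Labels are then encoded as dense integer ids in
lexicographic order, so the mapping is reproducible across runs.

**Normalization.** Each axis is z-scored with mean and standard deviation
computed over all training timesteps. Fitting these statistics on the
full dataset would leak held-out information into training, so the
package fits them per training fold only (`fit_normalizer()` /
`apply_normalizer()`); a constant axis is clamped to a standard deviation
of 10⁻⁸ with a warning rather than failing.

**Short-recording protocols.** Datasets that store one movement per file
(e.g. a single sport swing, with one label per recording) are windowed by
center-cropping recordings longer than `T` and edge-padding shorter ones
(`records_to_windows()`); pre-windowed benchmark records of a different
length are adapted by per-axis linear resampling (`resample_record()`).

## 3. The classifier

For a normalized window `X ∈ R^{T×D}` (default `D = 3` accelerometer
axes):

1. **Input projection.** `H0 = X W_p + b_p` lifts each timestep into a
   `d_model`-dimensional latent space. No positional encoding is added by
   default — the encoder equations carry none — but a sinusoidal encoding
   can be switched on for experimentation.
2. **Transformer encoder** (2 layers, post-norm). Each layer applies
   multi-head self-attention (scaled dot-product, scale `1/√d_k`,
   concatenation, output projection; no biases on the four projections) and a
   position-wise feed-forward network (ReLU, width `d_ff`), each wrapped
   as `LayerNorm(x + Sublayer(x))` — the *post-norm* order, applied
   exactly as written rather than the more common pre-norm variant.
3. **Selective-kernel (SK) branch.** Parallel grouped 1-D convolutions
   over time with kernel sizes {1, 3, 5, 7} (same-padded, groups = 4,
   batch-norm + ReLU per branch) capture motion motifs at several
   temporal scales. The branches are summed, average-pooled over time
   into a context vector `z`, compressed to a selection vector
   `s = ReLU(W₁ z)`, and a softmax over per-branch scores `w_k·s` yields
   one scalar weight per branch and sample; the branch outputs are mixed
   with these weights. We read the selection formula literally — one
   scalar per branch — rather than the per-channel selection used by
   image selective-kernel networks.
4. **Squeeze-enhanced axial (SEA) attention branch.** The latent sequence
   is reshaped to a 4-D map `(C_attn, H = T, W = d_model/C_attn)`:
   row attention runs along time, column attention along feature
   sub-bands, which is what makes the branch direction-aware. Queries,
   keys and values come from depthwise (kernel-3) convolutions; before
   attending, each axis is *squeezed* by mean-pooling over the other axis
   — this is what cuts the quadratic cost — with learnable additive
   positional embeddings of lengths `T` and `W`. Attention is single-head
   with `1/√C_attn` scaling; the attended sequences pass through
   depthwise convolutional encoders, are broadcast back over the squeezed
   axis, added to the value map, projected pointwise across channels, and
   passed through a sigmoid, so this branch's output lives in (0, 1).
   The sigmoid is applied literally as specified even though a bounded
   branch is unusual; a flag can disable it for experiments.
   A degenerate alternative reading — keeping the encoder output as a
   `(C = d_model, T, 1)` map — would make column attention a softmax over
   a singleton; the `C_attn` reshape (default 8) is this package's
   resolution of that ambiguity.
5. **Gated fusion.** A 1×1 convolution with one output channel on the
   encoder output, followed by a sigmoid, yields a per-timestep gate
   `G ∈ [0,1]`; the fused features are the convex combination
   `G·V_SK + (1−G)·V_SEA`, broadcast across channels. Forcing `G ≡ 1` or
   `G ≡ 0` routes a single branch through the head bit-for-bit — a
   property the test suite checks.
6. **Head.** Global average pooling over time, a linear map to `K`
   logits, and a softmax.

Weight initialization is fan-in uniform for linear/convolutional maps,
ones/zeros for normalization scales/shifts, zeros for biases and
positional embeddings; a single seed fixes every draw. All
backpropagation is hand-derived and checked against central-difference
gradients for every variant in the test suite; batched attention
(forward and backward) is implemented in C++ (RcppArmadillo) because it
dominates CPU cost.

### Ablation variants

`build_variant()` constructs the comparison models. The sources never
state what replaces a removed branch, so the package takes the
minimal-surgery readings and documents them: `No_SK` and `No_SEA` bypass
fusion entirely and feed the surviving branch to the head (the gate is
removed with the branch); `No_Gate` keeps both branches but fuses them
with a fixed 0.5/0.5 average; `No_Attn` pools the encoder output directly
(both branches and gate absent); `No_Filter` changes preprocessing only,
skipping the Butterworth and Savitzky–Golay stages. Parameter counts obey
`FullModel > {No_SK, No_SEA, No_Gate} > No_Attn` by construction.

## 4. Training and evaluation

Training minimizes categorical cross-entropy with Adam (learning rate
10⁻³, batch 64 by default). A stratified 10 % validation split drives
early stopping. The patience (10 epochs) acts on the *validation loss*:
with desk-scale validation splits of a dozen windows, validation accuracy
is a step function that plateaus long before the model converges, and
stopping on it froze training mid-descent in our experiments; the loss is
the continuous quantity the optimizer actually improves. The weights of
the best-loss epoch are restored.

Evaluation uses stratified k-fold cross-validation (default 5), with fold
assignment deterministic given the seed. Stratification is required at
small scales — a 30-recordings-per-class protocol cannot guarantee
per-class presence in unstratified folds. Normalization statistics and
the model are fitted per fold on that fold's training portion only.
Reported metrics are accuracy and macro-averaged precision, recall and
F1; macro averaging weights every class equally, which is the convention
that can push F1 above accuracy on imbalanced data. Fold averages are
unweighted means. Folds are split window-wise; subject-wise
(leave-one-subject-out) evaluation is out of scope.

## 5. The synthetic data generator

Real recordings cannot ship with the package, so `generator_config()` /
`generate_dataset()` produce fully synthetic sessions that keep every
pipeline property testable. Each activity class is a harmonic series
(three harmonics, relative amplitudes 1 / 0.5 / 0.25) at a class-specific
fundamental frequency, mixed across the three axes by a class-specific
rotation — so classes differ in *direction* as well as spectrum, which
exercises the axial branch — modulated by a slow amplitude envelope, plus
Gaussian sensor noise and a slow sinusoidal baseline drift. Labels change
only at segment boundaries.

The defaults emulate a six-activity waist-sensor protocol at 20 Hz:
fundamentals 0.5–2.3 Hz (inside the low-pass band), noise 0.08 g against
signal amplitudes around 1 g, drift 0.05 g with a 30 s period, activity
segments of 30–45 s, six sessions (about 200 label-consistent windows).
A record mode mirrors short-recording protocols (four classes × 30
single-label recordings). One master seed derives per-session seeds by
fixed offsets, so datasets are exactly reproducible.

What the generator does *not* emulate: inter-subject variability, sensor
placement drift, non-stationary activity tempo, gravity orientation
changes, and magnetometer/heart-rate channels. Passing the package's
accuracy tests on this data therefore demonstrates that the
implementation learns and that the pipeline is sound — not that the
architecture reaches any particular accuracy on real benchmarks.

A deliberately naive spectral-peak classifier
(`spectral_peak_classify()`) provides a floor: it reaches ≥95 % on the
default dataset, guaranteeing the data are learnable so that
model-accuracy tests are meaningful rather than vacuous.

## 6. Numerical choices and problem sizes

- Layer/batch normalization use ε = 10⁻⁵; batch-norm running statistics
  use momentum 0.1 and are used at evaluation time.
- Softmaxes are max-shifted; probabilities are clamped at 10⁻¹² inside
  the loss only.
- Grouped convolution weights are stored dense with a fixed
  block-diagonal mask applied at use, so structurally absent entries stay
  exactly zero through training; parameter counts count in-group entries
  only.
- The training-heavy experiments (cross-validation, ablation) use a
  reduced configuration — `d_model = 32`, 2 heads, `d_ff = 64`,
  `d_s = 8`, `C_attn = 8`, dropout 0 — on the ~200-window default
  synthetic dataset: small enough for a laptop-class CPU, large enough
  that every architectural component receives gradient and the ablation
  ordering is reproducible. The ablation uses batch 8 and 16 epochs
  (roughly 250-290 gradient steps) so that all six variants train to
  convergence, where the qualitative ordering is stable; the
  cross-validation experiment uses the batch-64 / 30-epoch budget of its
  protocol.
- `force_gate` fusion is computed through the same arithmetic path
  (`G·V_SK + (1−G)·V_SEA` with constant `G`), so the single-branch
  equivalence is an IEEE identity, not a shortcut.

## 7. Known limitations

- Only the accelerometer triple feeds the default model (`D = 3`);
  gyroscope and angle channels are decoded and exported but unused, and
  benchmark adapters expose only documented accelerometer columns.
- Window-wise cross-validation shares sessions between train and test
  folds; subject-wise generalization is not measured.
- The optimizer is plain Adam; schedulers, augmentation and
  regularization beyond dropout are out of scope.
- CPU-only: the implementation favors clarity and verifiability
  (hand-derived gradients, oracle tests) over throughput, and is not
  intended for GPU-scale benchmark training.
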