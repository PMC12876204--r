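# imunet

Human activity recognition (HAR) from wearable inertial measurement
units (IMUs), end to end: decode the JY61-style binary sensor protocol
into physical units, condition raw tri-axial signals, and classify
fixed-length windows with a transformer encoder augmented by a
selective-kernel multi-scale convolution branch, squeeze-enhanced axial
attention, and a learned gated fusion of the two. The package is aimed
at researchers working with low-cost wearable IMU streams (daily
activities, sports biomechanics) who need a transparent, CPU-trainable,
fully testable reference pipeline.

## The model

A normalized window `X ∈ R^{T×D}` (T = 200 timesteps, D = 3
accelerometer axes) is projected into a latent sequence
`H0 = X W_p + b_p` and refined by two post-norm transformer encoder
layers (`H1 = LayerNorm(H' + FFN(H'))`, `H' = LayerNorm(H0 + MHSA(H0))`).
Two branches then read `H1`:

- **Selective kernel (SK):** grouped 1-D convolutions over time with
  kernels k ∈ {1, 3, 5, 7}; per-branch features `U_k` are summed,
  pooled over time into a context `z`, and softmax weights
  `α_k ∝ exp(w_k·ReLU(W₁ z))` mix the branches:
  `V_SK = Σ_k α_k U_k`.
- **Squeeze-enhanced axial (SEA) attention:** the sequence reshaped to
  `(C_attn, T, d_model/C_attn)`; attention runs separately along rows
  (time) and columns (feature sub-bands), each axis first squeezed by
  mean-pooling over the other, with additive positional embeddings,
  depthwise convolutional Q/K/V and output encoders, and a final
  sigmoid-bounded pointwise projection: `V_SEA = σ(Proj(V + O_row + O_col))`.

A per-timestep gate `G = σ(Conv1×1(H1)) ∈ [0,1]` fuses the branches
convexly, `V = G·V_SK + (1−G)·V_SEA`, and global average pooling over
time feeds a softmax classification head. Training minimizes
cross-entropy with Adam (lr 0.001, batch 64), early-stopping on a
stratified 10 % validation split; evaluation is stratified k-fold
cross-validation with accuracy and macro precision/recall/F1. All
gradients are hand-derived (attention in C++ via RcppArmadillo) and
verified against numerical differentiation in the test suite.

## Worked example

```r
library(imunet)

# a synthetic six-activity dataset (quasi-periodic tri-axial signals
# with noise, drift and activity transitions; fully seeded)
gen <- generator_config()
ds  <- generate_dataset(gen)

# condition: low-pass + Savitzky-Golay, 200-step windows (stride 100),
# label-consistency filtering, lexicographic label encoding
w <- preprocess_sessions(ds$sessions)
w
#> <har_windows> 204 windows of 200 x 3 @ 20 Hz, 6 classes
#> # A tibble: 6 × 2
#>   label          n
#>   <chr>      <int>
#> 1 downstairs    33
#> 2 marching      38
#> 3 running       38
#> 4 standing      31
#> 5 upstairs      35
#> 6 walking       29

# 5-fold cross-validation of a CPU-scale configuration
cfg <- model_config(n_classes = 6, d_model = 32, h = 2, d_ff = 64,
                    d_s = 8, c_attn = 8, dropout = 0, seed = 1)
cv  <- run_cross_validation(w, cfg, train_config(epochs = 30, seed = 1))
glance(cv)
#> # A tibble: 1 × 7
#>   accuracy precision recall    f1 folds     n
#>      <dbl>     <dbl>  <dbl> <dbl> <int> <int>
#> 1        1         1      1     1     5   204
```

Each fold fits normalization statistics and a fresh model on its
training portion only; `glance()` reports unweighted fold means — here
the six synthetic activities are recovered perfectly in every fold.
`tidy(cv)` gives per-fold rows, `autoplot()` plots them, and
`plot_confusion(cv$confusion)` draws the pooled confusion matrix.

The binary-protocol path works the same way from a byte stream:

```r
bytes <- serialize_to_packets(ds$sessions[[1]])   # 33 bytes per sample
parse_stream(bytes)$diagnostics$n_samples         # decoded sample count
```

A thin command-line interface wraps the same functions
(`imunet synth | decode-stream | preprocess | train | evaluate | ablate | report`);
see `exec/imunet` and `?cli_main`.

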