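---
title: "Normatively regularized system identification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normatively regularized system identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybridsi)
```

## The problem

System identification (SI) fits a neuron's stimulus–response function from
recorded data; efficient coding (EC) asks what representations a sensory
system *should* build given the statistics of its natural environment.
`hybridsi` implements a model family that couples the two: a convolutional
encoding model predicting visual neurons' responses to dense noise shares its
convolutional filters with a convolutional autoencoder trained to efficiently
reconstruct natural-like images. The autoencoder acts as a *normative
regularizer*: to the extent that early visual receptive fields are shaped by
efficient coding of the environment, filters that serve image reconstruction
well should also be a good basis for predicting responses — especially when
neural training data are scarce.

Because no neural recordings ship with this package, a synthetic-data module
generates populations of linear–nonlinear (LN) model neurons with known
ground truth, so that every claim the package makes is checkable against a
planted answer.

## The SI branch

The factorized encoding model is, in order: one spatial convolutional layer
(16 filters of size `channels × 9 × 9`, **no padding**), one temporal
convolutional layer collapsing the `L` stimulus lags (`16 × 16 × L`), a fully
connected readout (one weight vector per neuron over the flattened feature
maps, plus a per-neuron bias), and an exponential output nonlinearity, so
predicted rates are strictly positive. On a 28×28 stimulus the readout sees
`16 · 20 · 20 = 6400` inputs; on 36×32 movie frames, `16 · 28 · 24 = 10752`.
The joint (3D) variant replaces the factorized pair by a single
spatio-temporal convolution (`16 × channels × L × 9 × 9`).

The training loss is the Poisson negative log-likelihood
$\sum_i (\hat r_i - r_i \log \hat r_i)$ plus an L2 penalty on the spatial
filters (weight $\alpha_1$), an L2 penalty on the temporal filters
($\alpha_2$) and an L1 penalty on the readout ($\beta$), with defaults
$(10, 10, 1/16)$ for the factorized model and $(100, -, 1/4)$ for the joint
model. The L2 penalties encourage smooth filters, the L1 readout a sparse
selection of feature-map locations. A per-neuron readout bias is included
(initialized at the log mean rate); with all weights zero the model predicts
a rate of exactly 1, which the tests exploit.

Two *basis-constrained* variants express the spatial filters as learned
weights over a fixed orthonormal basis: `make_pca_basis()` (channel-joint
eigenvectors of the 9×9 patch covariance of an image corpus) and
`make_dct_basis()` (2D-DCT basis images in JPEG-style zig-zag order
(0,0),(0,1),(1,0),(2,0),…, applied per chromatic channel). These serve as
low-pass-filtering controls: they smooth the filters without importing any
image statistics beyond second order.

## The EC branch

The autoencoder is deliberately shallow: encoder = one same-padded
convolution (the *shared* tensor) → ReLU → fully connected → ReLU; decoder =
fully connected → ReLU → transposed convolution → tanh, mapping back to the
stimulus range $[-1, 1]$. There is no classical unit bottleneck; capacity is
limited by Gaussian noise added to the encoder output during training
(`noise_sd`, default 0.1 in post-ReLU activation units, off at evaluation)
and an L1 penalty on that activation ($\beta_2$, default 1/16), with L2
penalties on the conv and deconv filters ($\alpha_3$, default 1000)
encouraging smooth kernels. The loss is the summed squared reconstruction
error plus those penalties. Same padding is forced by the architecture's
printed activation size (16×28×28 from a 28×28 input); the SI branch stays
unpadded — the asymmetry is intentional and documented here.

The 3D variants consume 8-frame movie clips: *past encoding* reconstructs
the clip's 7th frame; *future prediction* predicts the unseen 8th frame from
the first 7, with the 8th input slot filled by the per-channel mean of the
first 7. The decoder reconstructs a single frame, so the deconvolution
tensor stays 2D (`16 × channels × 9 × 9`) in both 3D modes.

`latent_dim` is not architecture-critical (the bandwidth constraint comes
from noise plus L1, not dimensionality); the default is 512, and the
package's reference experiments use 64 — at the experiments' reduced problem
sizes this preserves the regularization behavior at a fraction of the cost.

## The hybrid objective

The two branches share one convolutional filter tensor — the same parameter
object, not a copy (parameters live in R environments, so mutating the
filters through either branch is visible in the other). The total loss is

$$L = w\,L_{SI} + (1-w)\,L_{EC}$$
$$L_{SI} = \Big(\textstyle\sum_i (\hat r_i - r_i \log \hat r_i) +
  \alpha_1\|w_{cs}\|^2 + \alpha_2\|w_{ct}\|^2/w + \beta_1\|w_f\|_1/w\Big)/N_1$$
$$L_{EC} = \Big(\textstyle\sum_j (x_j - \hat x_j)^2 + \alpha_3\|w_{cs}\|^2 +
  \alpha_3\|w_d\|^2/(1-w) + \beta_2\|h\|_1/(1-w)\Big)/N_2$$

The $/w$ and $/(1-w)$ denominators keep the *branch-private* regularization
(temporal filters, readout, deconvolution, latent activation) at constant
effective strength as $w$ varies, so sweeping $w$ changes only the relative
pull of the two data terms (and of the two shared-filter penalties) on the
shared filters. At $w \in \{0, 1\}$ the values $10^{-8}$ and $1-10^{-8}$ are
substituted to avoid division by zero; at $w=1$ the model behaves as the
stand-alone SI model, at $w=0$ as the stand-alone autoencoder.

**Normalization.** $N_1$ is the number of neurons and $N_2$ the number of
images (or clips) in the EC corpus — dataset-level constants, not mini-batch
counts. During stochastic training each mini-batch's data terms are scaled
up by (dataset size / batch size) before the division, making every step an
unbiased estimate of the dataset-level objective above. This matters: if
$N_2$ were the batch size, the fixed penalty $\alpha_3\|w_{cs}\|^2/N_2$
would act as a per-step weight decay one to two orders of magnitude too
strong and simply extinguish the shared filters.

**Optimization.** Adam at learning rate $10^{-4}$, one gradient step per
SI/EC mini-batch pair (SI batches of 32 response samples, EC batches of
16–32 images, cycled independently). SI mini-batches are contiguous temporal
blocks with shuffled block order: clips inside a block overlap in all but
one frame, so a batch touches ~`batch + L` stimulus frames instead of
`batch × L`, which is what makes CPU training practical; block-shuffled SGD
is a standard variant for strongly overlapping windows. Training runs for at
most `max_epochs` (default 100) and stops early when the validation metric —
mean single-trial correlation between prediction and the validation trace —
fails to improve for `patience` (default 3) consecutive epochs; the
best-validation snapshot is returned. When only a fraction of the training
segment is used (the data-efficiency protocol takes the *leading contiguous*
fraction; validation and test are untouched), the learning rate is doubled.
Divergent (non-finite) losses abort with a diagnostic rather than continuing.

Basis-constrained filters are supported for the stand-alone SI model only;
in hybrid mode the shared tensor must be free for both branches to shape it.

## Synthetic data: what it emulates, and what it does not

- `generate_binary_noise()`: chromatic (UV/green) binary dense noise, every
  pixel independently ±1 — coded as ±1 rather than 0/1 so all model inputs
  live in the tanh range of the decoder.
- `generate_structured_images()`: the stand-in for natural images. Each
  image is synthesized with an exact $1/f^{\gamma}$ radial amplitude
  spectrum (random phases), passed through a pointwise signed square
  ($x \mapsto x|x|$) to create sparse, localized events — i.e., structure
  beyond second order — and the target spectrum is then re-imposed, so the
  higher-order structure lives entirely in the phases while the slope
  contract ($\pm 0.15$ of the requested exponent) holds exactly. Chromatic
  channels are mixed from correlated underlying fields (default correlation
  0.8). What this corpus does **not** have: occlusion edges, perspective,
  object content, or the luminance distribution of real habitats — so a
  passing ordering here shows the machinery responds to second- vs
  higher-order statistics as intended, not that it reproduces any specific
  natural-image benefit quantitatively.
- `phase_scramble()`: randomizes Fourier phases (via the phases of a random
  real field, which guarantees Hermitian symmetry) while preserving each
  channel's amplitude spectrum exactly and leaving the DC component
  untouched — the classic control that keeps second-order and destroys
  higher-order statistics.
- `simulate_ln_population()`: LN neurons with difference-of-Gaussians
  spatial receptive fields (center σ ~ U(1.2, 2) px, surround at 2σ, ON/OFF
  mixed), biphasic unit-norm temporal kernels, a softplus output
  nonlinearity (gain 2, threshold 0.5) applied to a unit-variance drive, and
  additive Gaussian trial noise clipped at zero — matching continuous,
  nonnegative event-rate traces rather than spike counts. The default
  `trial_noise_sd = 1.0` was chosen so that the simulated quality index
  (median ≈ 0.5 at 6 test repeats) falls in the range that the QI > 0.25
  inclusion rule would retain in real recordings. Chromatic dominance is
  population-tagged: "ventral" populations weight the UV channel, "dorsal"
  the green channel.
- `simulate_direction_trials()`: moving-bar responses at 8 directions, a
  shared temporal profile scaled by a von Mises-modulated amplitude
  (`tuning_strength` 0 = untuned, 1 = concentrated), plus trial noise.

## Analysis choices

- **Receptive fields** are estimated as the gradient of the *pre-exponential*
  output (log rate) with respect to the input at an all-zero stimulus; at
  the blank input the rate gradient is proportional, and the log-rate avoids
  an arbitrary scale. The spatio-temporal gradient is factorized by SVD of
  its `[lags × pixels]` matricization with channels stacked along pixels
  (one temporal component for all channels, matching the result container);
  the temporal component has unit norm and its largest-magnitude lag is made
  positive, so the spatial map carries polarity and magnitude.
- **Filter plausibility** is the R² of an elliptical 2D Gaussian
  (amplitude, center, σx, σy, rotation, offset) fit by Levenberg–Marquardt
  least squares, initialized at the absolute peak with σ = 2 px and 4
  jittered restarts; R² is clipped to [0, 1] and set to 0 whenever
  max(σx, σy) exceeds the filter size — a fit that leaves the support is no
  evidence of a Gaussian-shaped filter. The score is computed on the
  dominant chromatic channel (largest peak absolute value; ties go to the
  lower index, with a message).
- **Direction selectivity**: SVD of the trial-averaged `[time × direction]`
  matrix gives a temporal and a directional component; the directional
  component is sign-fixed to nonnegative sum and clipped at zero, and the
  index is the length of the tuning-weighted vector sum over the 8
  directions *normalized by the total tuning mass* (so DSI ∈ [0, 1]).
  Without the normalization, tuning spread over adjacent directions can
  outscore tuning concentrated at a single direction, which inverts the
  statistic's intent; the normalization does not affect the permutation
  test's calibration, which follows from label exchangeability alone.
  P-values use the add-one estimator $(b+1)/(n+1)$, as does the two-sided
  sign-flip permutation test for paired model scores.
- **Predictive performance** is the Pearson correlation between the
  predicted trace and the repeat-averaged test response (single-trial traces
  for validation). Error bars are percentile bootstrap intervals (2.5/97.5)
  of the mean.

## Reference experiment sizes

The package's own experiments (tests and `scripts/acceptance.R`) run at
sizes chosen to finish on one CPU core while preserving the qualitative
contrasts:

- *Recovery*: 50 neurons, 2400 frames of 28×28 noise (plus a 50-frame test
  sequence repeated 6 times), stand-alone SI, ≤ 30 epochs. Median
  correlation between gradient-RF spatial components and planted DoG fields
  is the parameter-recovery metric. Penalty weights for this experiment were
  selected by the same protocol that produced the published defaults — a
  grid search on validation correlation — applied to this benchmark: scaling
  all three stand-alone penalties by {1, 10, 50, 100, 250, 500, 1000}
  selects the 250× point (α₁ = α₂ = 2500, β ≈ 15.6), where validation CC
  roughly doubles relative to the unscaled values. The noisy 50-neuron
  population simply sits at a different point of the bias–variance trade-off
  than the recordings behind the default constants; the selection used
  validation CC only, never the recovery metric.
- *Model comparison*: 30 neurons on 16×16 noise (1250 frames), EC corpus of
  300 images, training restricted to the leading 40% of the training
  segment, 5 seeds per model, ≤ 25 epochs, latent 64, EC batches of 16.
  Hybrid branch weights are fixed at w = 0.2 (structured), 0.3
  (phase-scrambled) and 0.4 (white noise) — each input type's optimum, which
  a validation sweep at this scale also selects (`sweep_hyperparameter()`).
  The expected pattern: test CC and filter R² both order structured ≥
  phase-scrambled ≥ white-noise > stand-alone SI at restricted data, and the
  hybrid−SI gap shrinks when the full training segment is used.

These sizes are this package's choices for its reference runs; all of them
are plain function arguments, and the full-scale settings (28×28, 96+
neurons, 100 epochs, latent 512) remain the documented defaults.

## Known limitations

- The trainer is plain R + BLAS with small compiled kernels; it is meant for
  the tens-of-neurons, thousands-of-frames regime, not for GPU-scale data.
- The synthetic corpus carries 1/f-plus-sparse-events structure only; claims
  about *real* natural-scene statistics cannot be settled with it.
- Basis-constrained (PCA/DCT) filters apply to the stand-alone SI model; the
  hybrid couples only free filter tensors.
- Persistence uses CSV/JSON (`write_report()`); array containers such as
  HDF5 are not written by this package.
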