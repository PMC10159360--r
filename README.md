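# hybridsi

Convolutional encoding models for visual neurons whose shared filters are
regularized by an efficient-coding autoencoder.

## What this package is for

Neural *system identification* (SI) fits a neuron's stimulus–response
function from recordings — here with a convolutional network: a spatial
convolution (16 unpadded 9×9 filters), a temporal convolution over stimulus
lags, a fully connected readout and an exponential output, trained with a
Poisson loss. *Efficient coding* (EC) holds that early visual
representations are shaped by the need to transmit natural scenes through
limited bandwidth — here instantiated as a shallow convolutional autoencoder
whose capacity is limited by encoder noise and a sparsity penalty rather
than a unit bottleneck.

`hybridsi` couples the two in a single *hybrid* model: both branches share
one convolutional filter tensor and are trained jointly on the weighted
objective

    L = w · L_SI + (1 − w) · L_EC

    L_SI = ( Σᵢ (r̂ᵢ − rᵢ log r̂ᵢ) + α₁‖w_cs‖² + α₂‖w_ct‖²/w + β₁‖w_f‖₁/w ) / N₁
    L_EC = ( Σⱼ (xⱼ − x̂ⱼ)²      + α₃‖w_cs‖² + α₃‖w_d‖²/(1−w) + β₂‖h‖₁/(1−w) ) / N₂

so that sweeping the branch weight `w` trades neural prediction against
image reconstruction on the shared filters while all branch-private
regularization keeps constant strength (`1e-8` is substituted at `w ∈ {0,1}`).
The scientific question the package operationalizes: does giving the
encoding model access to natural-like image statistics improve its response
predictions and make its filters more biologically plausible (more
Gaussian/center-surround), especially when neural data are scarce?

Everything runs on synthetic data with planted ground truth: chromatic
binary dense noise, linear–nonlinear model neurons with
difference-of-Gaussians receptive fields and biphasic temporal kernels, 1/f
image corpora with higher-order phase structure (plus phase-scrambled and
white-noise controls), and direction-tuned moving-bar trials. The analysis
toolbox includes gradient-based receptive-field estimation with SVD
factorization, an elliptical-Gaussian filter-plausibility score, a response
quality index, direction-selectivity and model-comparison permutation tests,
and bootstrap intervals.

## Worked example

```r
library(hybridsi)

# Simulated benchmark: chromatic binary noise, LN neurons, image corpora
bench <- make_benchmark(n_neurons = 30, n_frames = 1250, n_images = 300,
                        height = 16, width = 16, seed = 1)
bench$data$responses
#> <response_set> 30 neurons; train 1100, val 100 frames; test 6 repeats x 50 frames; median QI 0.540

# Stand-alone encoding model vs. hybrid with a structured-image autoencoder,
# both restricted to the leading 40% of the training segment
mk <- function(w) hybrid_config(w = w, si = si_config(),
                                ec = ec_config(latent_dim = 64),
                                batch_ec = 16, max_epochs = 25, patience = 5,
                                data_fraction = 0.4)
report <- run_experiment(
  bench$data,
  models = list(si = list(config = mk(1)),
                hybrid = list(config = mk(0.2),
                              ec_corpus = bench$corpora$structured)),
  seeds = 1:2)
print(report$summary, row.names = FALSE)
#>   model   mean_cc     cc_lo     cc_hi   mean_r2
#>      si 0.1934605 0.1481413 0.2393964 0.1289461
#>  hybrid 0.2973881 0.2486313 0.3473425 0.1739492
print(report$comparisons, row.names = FALSE)
#>  model_a model_b     delta   p_value
#>       si  hybrid 0.1039275 9.999e-05
```

With only 40% of the training data, the hybrid model predicts held-out test
responses substantially better than the stand-alone encoding model
(mean Pearson correlation 0.30 vs 0.19 against the repeat-averaged test
response; two-sided sign-flip permutation test over neurons, p ≈ 1e-4), and
its shared filters are more Gaussian-shaped (mean elliptical-Gaussian R²
0.17 vs 0.13).

```r
# Receptive field of one neuron from the trained hybrid model
m <- report$models[["hybrid/1"]]
rf <- estimate_rf(m, neuron = 3)
round(rf$singular_value_ratio, 3)
#> [1] 0.26
round(cor(as.vector(rf$spatial_component),
          as.vector(bench$neurons[[3]]$spatial_rf)), 3)
#> [1] 0.775
```

The gradient receptive field of a neuron correlates with the planted
difference-of-Gaussians field it was simulated from.

A thin command-line wrapper for simulation, training, weight sweeps and
data-efficiency curves is installed at
`system.file("cli", "hybridsi.R", package = "hybridsi")`.

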