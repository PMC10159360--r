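Package: hybridsi
Title: Hybrid System Identification with Efficient-Coding Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Convolutional encoding models for visual neurons whose shared
    filters are regularized by a convolutional autoencoder trained to
    efficiently represent natural-like stimuli. Provides system-identification
    models with factorized spatial/temporal or joint spatio-temporal filters
    and Poisson loss, basis-constrained (PCA/DCT) variants, a noisy sparse
    autoencoder branch with past-encoding and future-prediction targets,
    joint training of both branches on shared convolutional filters, synthetic
    retinal data generators (chromatic binary dense noise, 1/f image corpora,
    linear-nonlinear model neurons, moving-bar direction trials), trace
    preprocessing and response-reliability metrics, gradient-based
    receptive-field estimation with SVD factorization, Gaussian-fit filter
    plausibility scores, direction-selectivity permutation tests, and
    permutation/bootstrap model-comparison statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    signal,
    minpack.lm,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
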