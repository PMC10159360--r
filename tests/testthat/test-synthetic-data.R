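test_that("binary dense noise has the right geometry, values and determinism", {
  s <- generate_binary_noise(28, 28, 100, 2, 5, seed = 0)
  expect_equal(dim(s$frames), c(100, 2, 28, 28))
  expect_true(all(s$frames %in% c(-1, 1)))
  s2 <- generate_binary_noise(28, 28, 100, 2, 5, seed = 0)
  expect_identical(s$frames, s2$frames)
  s3 <- generate_binary_noise(28, 28, 100, 2, 5, seed = 1)
  expect_false(identical(s$frames, s3$frames))
  # minimal case
  s1 <- generate_binary_noise(1, 1, 1, 1, 5, seed = 0)
  expect_true(s1$frames[1, 1, 1, 1] %in% c(-1, 1))
  expect_error(generate_binary_noise(0, 28, 10, 2, 5), "height")
})

test_that("binary noise is unbiased and temporally white (4 SE bounds)", {
  s <- generate_binary_noise(28, 28, 10000, 2, 5, seed = 1)
  n <- length(s$frames)
  # per-pixel mean of +-1 draws: SE = 1/sqrt(n_frames) per pixel; test the
  # grand mean and a sample of per-pixel means
  expect_lt(abs(mean(s$frames)), 4 / sqrt(n))
  px <- s$frames[, 1, 14, 14]
  expect_lt(abs(mean(px)), 4 / sqrt(length(px)))
  r1 <- cor(px[-length(px)], px[-1])
  expect_lt(abs(r1), 4 / sqrt(length(px)))
})

test_that("structured corpora hit the requested spectral slope", {
  ci <- generate_structured_images(100, 28, 28, 1.0, 0.8, seed = 0)
  expect_equal(dim(ci$images), c(100, 2, 28, 28))
  expect_lte(max(abs(ci$images)), 1)
  slope <- radial_slope(ci$images)
  expect_lt(abs(slope - (-1.0)), 0.15)
  # steeper spectrum
  ci2 <- generate_structured_images(60, 28, 28, 1.5, 0.8, seed = 1)
  expect_lt(abs(radial_slope(ci2$images) - (-1.5)), 0.2)
})

test_that("white-noise limit and chromatic correlation extremes", {
  w <- generate_structured_images(60, 28, 28, 0, 0, nonlinearity = "none",
                                  seed = 2)
  expect_identical(w$provenance, "white_noise")
  expect_lt(abs(radial_slope(w$images)), 0.1)
  same <- generate_structured_images(5, 28, 28, 1.0, 1, seed = 3)
  for (i in 1:5)
    expect_equal(same$images[i, 1, , ], same$images[i, 2, , ],
                 tolerance = 1e-10)
  expect_error(generate_structured_images(5, 28, 28, 1.0, 1.2), "chromatic")
})

test_that("phase scrambling preserves amplitude spectra exactly", {
  ci <- generate_structured_images(4, 16, 16, 1.0, 0.5, seed = 4)
  sc <- phase_scramble(ci, seed = 1, rescale = FALSE)
  for (i in 1:4) for (c in 1:2) {
    a_in <- Mod(fft(matrix(ci$images[i, c, , ], 16, 16)))
    a_out <- Mod(fft(matrix(sc$images[i, c, , ], 16, 16)))
    expect_lt(max(abs(a_out - a_in)) / max(a_in), 1e-8)
  }
  expect_identical(sc$provenance, "phase_scrambled")
})

test_that("phase scrambling leaves constants alone and gaussianizes pixels", {
  const <- image_corpus(array(0.5, c(1, 1, 12, 12)), "structured")
  sc <- phase_scramble(const, seed = 1, rescale = FALSE)
  expect_equal(sc$images, const$images, tolerance = 1e-12)
  ci <- generate_structured_images(100, 28, 28, 1.0, 0.8, seed = 5)
  sc2 <- phase_scramble(ci, seed = 2)
  k_in <- mean(sapply(1:100, function(i) excess_kurtosis(ci$images[i, , , ])))
  k_out <- mean(sapply(1:100, function(i) excess_kurtosis(sc2$images[i, , , ])))
  expect_lt(abs(k_out), abs(k_in))   # driven toward the Gaussian value 0
  # second-order structure is retained
  expect_lt(abs(radial_slope(sc2$images) - radial_slope(ci$images)), 0.2)
})

test_that("LN population simulation honors shapes and the noiseless limit", {
  stim <- generate_binary_noise(12, 12, 260, 2, 5, seed = 1)
  sim <- simulate_ln_population(10, stim,
                                rf_params = list(n_lags = 4,
                                                 trial_noise_sd = 0),
                                n_test_repeats = 4, test_frames = 20, seed = 2)
  rs <- sim$responses
  expect_equal(dim(rs$test_block), c(10, 4, 20))
  expect_equal(nrow(rs$train_traces), 10)
  expect_equal(length(rs$stim_split$train) + length(rs$stim_split$val) +
                 length(rs$stim_split$test), 260)
  # zero trial noise: repeats identical, QI exactly 1
  for (i in 1:10) {
    expect_equal(rs$test_block[i, 1, ], rs$test_block[i, 4, ])
    expect_equal(rs$qi_noise[i], 1, tolerance = 1e-12)
  }
  # ground truth returned with unit-norm kernels
  expect_length(sim$neurons, 10)
  expect_equal(sum(sim$neurons[[1]]$temporal_kernel^2), 1, tolerance = 1e-12)
  expect_error(simulate_ln_population(3, generate_binary_noise(12, 12, 30),
                                      test_frames = 20),
               "too short")
})

test_that("spike-triggered average recovers a simulated neuron's spatial RF", {
  stim <- generate_binary_noise(20, 20, 2400, 2, 5, seed = 3)
  # pure-ON cells, as in the classic STA setting
  sim <- simulate_ln_population(3, stim,
                                rf_params = list(n_lags = 4, off_fraction = 0),
                                n_test_repeats = 2, test_frames = 20, seed = 4)
  # STA oracle, independent of the model code: correlate the response with
  # the stimulus filtered by the known temporal kernel
  for (i in 1:3) {
    nrn <- sim$neurons[[i]]
    kern <- nrn$temporal_kernel
    L <- length(kern)
    tr <- sim$responses$train_traces[i, ]
    tr <- tr - mean(tr)
    sta <- array(0, dim(nrn$spatial_rf))
    for (c in 1:2) {
      pix <- matrix(stim$frames[seq_along(tr), c, , ], nrow = length(tr))
      filt <- apply(pix, 2, function(v)
        stats::filter(v, rev(kern), method = "convolution", sides = 1))
      filt[is.na(filt)] <- 0
      sta[c, , ] <- matrix(crossprod(filt, tr), 20, 20)
    }
    r <- abs(cor(as.vector(sta), as.vector(nrn$spatial_rf)))
    expect_gt(r, 0.6)
  }
})

test_that("direction trials follow the tuning-strength contract", {
  # untuned: all directions share one mean amplitude
  cells <- simulate_direction_trials(1, tuning_strengths = 0, n_trials = 50,
                                     noise_sd = 0.05, seed = 1)
  m <- apply(cells[[1]]$responses, 2, mean)
  expect_lt(diff(range(m)) / mean(m), 0.15)
  # perfect tuning, zero noise: response peaks at the preferred direction
  tuned <- simulate_direction_trials(1, tuning_strengths = 1, n_trials = 3,
                                     noise_sd = 0, seed = 2)
  amp <- apply(tuned[[1]]$responses, 2, max)
  pref <- attr(tuned[[1]], "preferred_angle")
  dirs <- tuned[[1]]$directions
  expect_equal(which.max(amp),
               which.min(pmin(abs(dirs - pref), 360 - abs(dirs - pref))))
  d0 <- ds_test(tuned[[1]], n_perm = 99, seed = 1)
  expect_gt(d0$ds_index, 0.5)
  expect_lte(d0$p_value, 0.05)
  expect_error(simulate_direction_trials(2, 0.5, n_trials = 1), "n_trials")
})

test_that("all generators emit values in [-1, 1] and are seed-deterministic", {
  gens <- list(
    function(s) generate_binary_noise(10, 10, 20, 2, 5, seed = s)$frames,
    function(s) generate_structured_images(5, 16, 16, 1, 0.5, seed = s)$images,
    function(s) generate_white_noise_images(5, 16, 16, seed = s)$images)
  for (g in gens) {
    a <- g(11); b <- g(11)
    expect_identical(a, b)
    expect_lte(max(abs(a)), 1)
    expect_true(all(is.finite(a)))
  }
})
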