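test_that("gradient receptive fields equal a numerical input gradient", {
  td <- tiny_dataset()
  cfg <- tiny_hybrid_config(w = 1, max_epochs = 1)
  m <- train_model(td$data, NULL, cfg, seed = 1)
  g <- attr(m$si, "geometry")
  L <- cfg$si$n_lags
  rf <- estimate_rf(m, 2)
  expect_equal(dim(rf$spatiotemporal), c(g$C, L, g$H, g$W))
  # oracle: forward differences of the log rate around the blank input
  z_of <- function(clip) log(si_forward(m$si, cfg$si, clip)[2, 1])
  blank <- array(0, c(g$C, L, g$H, g$W))
  eps <- 1e-4
  idx <- rbind(c(1, 1, 3, 4), c(2, 2, 7, 7), c(1, 4, 10, 2), c(2, 3, 5, 11))
  for (r in seq_len(nrow(idx))) {
    pert <- blank
    pert[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]] <- eps
    num <- (z_of(pert) - z_of(blank)) / eps
    expect_equal(num, rf$spatiotemporal[idx[r, 1], idx[r, 2], idx[r, 3],
                                        idx[r, 4]],
                 tolerance = 1e-4)
  }
  expect_error(estimate_rf(m, 99), "neuron")
})

test_that("SVD factorization is exact for rank-1 fields and normalized", {
  ns <- asNamespace("hybridsi")
  set.seed(3)
  sp <- array(rnorm(2 * 9 * 9), c(2, 9, 9))
  tk <- rnorm(5)
  rf <- array(0, c(2, 5, 9, 9))
  for (l in 1:5) rf[, l, , ] <- tk[l] * sp
  fz <- ns$factorize_rf(rf)
  expect_equal(fz$singular_value_ratio, 1, tolerance = 1e-10)
  expect_equal(sum(fz$temporal_component^2), 1, tolerance = 1e-12)
  # the temporal sign convention puts the biggest lag positive and the
  # spatial map carries polarity and magnitude
  expect_gt(fz$temporal_component[which.max(abs(fz$temporal_component))], 0)
  recon <- array(0, dim(rf))
  for (l in 1:5) recon[, l, , ] <- fz$temporal_component[l] *
    fz$spatial_component
  expect_equal(recon, rf, tolerance = 1e-10)
})

test_that("trained models recover planted receptive fields", {
  stim <- generate_binary_noise(16, 16, 1300, 2, 5, seed = 11)
  sim <- simulate_ln_population(8, stim,
                                rf_params = list(n_lags = 5,
                                                 trial_noise_sd = 0.4),
                                n_test_repeats = 3, test_frames = 25,
                                seed = 12)
  cfg <- hybrid_config(w = 1,
                       si = si_config(n_filters = 8, kernel_size = 7,
                                      n_lags = 5),
                       max_epochs = 10, patience = 4, batch_si = 32)
  m <- train_model(list(stimulus = stim, responses = sim$responses), NULL,
                   cfg, seed = 2)
  cors <- vapply(1:8, function(i) {
    abs(cor(as.vector(estimate_rf(m, i)$spatial_component),
            as.vector(sim$neurons[[i]]$spatial_rf)))
  }, numeric(1))
  expect_gt(median(cors), 0.6)
})

test_that("gaussian fits score exact Gaussians, reject the oversize rule", {
  grid <- expand.grid(y = 1:9, x = 1:9)
  gauss <- matrix(exp(-((grid$y - 5)^2 + (grid$x - 4)^2) / (2 * 2^2)), 9, 9)
  fit <- gaussian_fit_r2(gauss)
  expect_gte(fit$r_squared, 0.999)
  expect_equal(unname(fit$center), c(4, 5), tolerance = 0.05)
  # sigma 20 px on a 9x9 grid: fitted sigma exceeds the filter -> forced 0
  wide <- matrix(exp(-((grid$y - 5)^2 + (grid$x - 5)^2) / (2 * 20^2)), 9, 9)
  expect_equal(gaussian_fit_r2(wide, max_sigma = 9)$r_squared, 0)
  # sign and scale invariance
  expect_equal(gaussian_fit_r2(-3.7 * gauss)$r_squared, fit$r_squared,
               tolerance = 1e-4)
  expect_equal(gaussian_fit_r2(gauss / 100)$r_squared, fit$r_squared,
               tolerance = 1e-4)
  # degenerate input
  expect_equal(gaussian_fit_r2(matrix(1, 9, 9))$r_squared, 0)
})

test_that("iid noise filters rarely look Gaussian", {
  set.seed(4)
  r2 <- replicate(60, gaussian_fit_r2(matrix(rnorm(81), 9, 9))$r_squared)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_lt(median(r2), 0.5)
})

test_that("dominant channel follows peak energy with a lower-index tie rule", {
  sp <- array(0, c(2, 9, 9))
  sp[1, 5, 5] <- 10; sp[2, 5, 5] <- 1
  expect_equal(dominant_channel(sp), 1L)
  sp[2, 5, 5] <- -20
  expect_equal(dominant_channel(sp), 2L)
  tie <- array(0, c(2, 9, 9)); tie[1, 2, 2] <- 1; tie[2, 3, 3] <- 1
  expect_message(ch <- dominant_channel(tie), "tie")
  expect_equal(ch, 1L)
})

test_that("simulated UV-dominant populations are flagged UV-dominant", {
  stim <- generate_binary_noise(14, 14, 400, 2, 5, seed = 13)
  sim <- simulate_ln_population(20, stim,
                                rf_params = list(n_lags = 4,
                                                 population = "ventral"),
                                n_test_repeats = 2, test_frames = 20,
                                seed = 14)
  doms <- vapply(sim$neurons, function(n) dominant_channel(n$spatial_rf),
                 integer(1))
  expect_gt(mean(doms == 1L), 0.9)
})

test_that("predictive correlation has Pearson's invariances and null behavior", {
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(predictive_cc(x, x), 1)
  expect_equal(predictive_cc(3 * x + 2, x), 1)
  expect_error(predictive_cc(rep(1, 10), rnorm(10)), "variance")
  set.seed(5)
  nulls <- replicate(200, predictive_cc(rnorm(1000), rnorm(1000)))
  expect_gt(mean(abs(nulls) < 0.1), 0.9)
})

test_that("direction-selectivity index behaves at the tuning extremes", {
  # perfectly uniform tuning: the 8 unit vectors cancel
  flat <- array(rep(rep(1:5 / 5, 8), 3), c(5, 8, 3))
  d <- ds_test(flat, n_perm = 49, seed = 1)
  expect_lt(d$ds_index, 1e-10)
  # response at one direction only: index equals the full tuning mass (1 for
  # a unit-norm directional component), minimal attainable p
  one <- array(0, c(5, 8, 3))
  one[, 3, ] <- rep(1:5 / 5, 3)
  d1 <- ds_test(one, n_perm = 99, seed = 1)
  expect_equal(d1$ds_index, 1, tolerance = 1e-10)
  expect_lte(d1$p_value, 0.05)   # near the attainable floor of 1/(n_perm+1)
  expect_error(ds_test(array(0, c(5, 1, 3))), "directions")
})

test_that("model-comparison permutation test hits its endpoints", {
  a <- rnorm(30)
  expect_equal(compare_models(a, a, n_perm = 200, seed = 1), 1)
  b <- a + 10 * sd(a)
  expect_equal(compare_models(a, b, n_perm = 200, seed = 1), 1 / 201,
               tolerance = 1e-12)
  expect_error(compare_models(1, 1:2), "equal length")
})

test_that("bootstrap intervals are ordered and collapse for constants", {
  expect_equal(unname(bootstrap_ci(rep(3.2, 10), n_boot = 50, seed = 1)),
               c(3.2, 3.2))
  set.seed(6)
  v <- rnorm(100)
  ci <- bootstrap_ci(v, n_boot = 500, seed = 2)
  expect_lte(ci["lo"], mean(v))
  expect_gte(ci["hi"], mean(v))
  expect_error(bootstrap_ci(numeric(0)), "at least")
})

test_that("bootstrap coverage of the mean is near nominal", {
  set.seed(7)
  hits <- replicate(600, {
    v <- rnorm(100)
    ci <- bootstrap_ci(v, n_boot = 500, seed = sample.int(1e6, 1))
    ci["lo"] <= 0 && ci["hi"] >= 0
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})
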