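test_that("hybrid loss matches the written-out weighted objective", {
  set.seed(1)
  for (i in 1:20) {
    w <- sample(c(0, 1, runif(3)), 1)
    a1 <- runif(1, 0, 20); a2 <- runif(1, 0, 20); b1 <- runif(1, 0, 1)
    a3 <- runif(1, 0, 2000); b2 <- runif(1, 0, 1)
    cfg <- hybrid_config(w = w,
                         si = si_config(alpha1 = a1, alpha2 = a2, beta = b1),
                         ec = ec_config(alpha = a3, beta = b2))
    si_terms <- list(poisson = runif(1, 0, 100), l2_shared = runif(1),
                     l2_temporal = runif(1), l1_readout = runif(1),
                     n = sample(10:100, 1))
    ec_terms <- list(mse = runif(1, 0, 500), l2_shared = si_terms$l2_shared,
                     l2_deconv = runif(1), l1_latent = runif(1, 0, 50),
                     n = sample(10:100, 1))
    got <- hybrid_loss(si_terms, ec_terms, cfg)
    want <- hybrid_loss_bruteforce(w, si_terms$poisson, si_terms$l2_shared,
                                   si_terms$l2_temporal, si_terms$l1_readout,
                                   si_terms$n, ec_terms$mse,
                                   ec_terms$l2_deconv, ec_terms$l1_latent,
                                   ec_terms$n, a1, a2, b1, a3, b2)
    expect_lt(abs(got - want) / max(abs(want), 1e-12), 1e-12)
  }
})

test_that("hybrid loss algebra: vanishing and single-term cases", {
  cfg <- hybrid_config(w = 0.5, si = si_config(alpha1 = 1),
                       ec = ec_config(alpha = 1))
  zero_si <- list(poisson = 0, l2_shared = 0, l2_temporal = 0,
                  l1_readout = 0, n = 10)
  zero_ec <- list(mse = 0, l2_shared = 0, l2_deconv = 0, l1_latent = 0, n = 20)
  expect_equal(hybrid_loss(zero_si, zero_ec, cfg), 0)
  # one nonzero shared filter, alpha1 = alpha3 = 1, everything else zero:
  # total = 0.5 * ||w||^2 / N1 + 0.5 * ||w||^2 / N2
  l2 <- 7.3
  si1 <- modifyList(zero_si, list(l2_shared = l2))
  ec1 <- modifyList(zero_ec, list(l2_shared = l2))
  expect_equal(hybrid_loss(si1, ec1, cfg), 0.5 * l2 / 10 + 0.5 * l2 / 20,
               tolerance = 1e-12)
})

test_that("w = 0 and w = 1 substitute the 1e-8 epsilon instead of dividing by zero", {
  cfg1 <- hybrid_config(w = 1)
  si_terms <- list(poisson = 10, l2_shared = 1, l2_temporal = 1,
                   l1_readout = 1, n = 5)
  ec_terms <- list(mse = 100, l2_shared = 1, l2_deconv = 1, l1_latent = 1,
                   n = 7)
  v1 <- hybrid_loss(si_terms, ec_terms, cfg1)
  expect_true(is.finite(v1))
  cfg1b <- hybrid_config(w = 1 - 1e-8)
  expect_equal(v1, hybrid_loss(si_terms, ec_terms, cfg1b), tolerance = 1e-12)
  cfg0 <- hybrid_config(w = 0)
  expect_equal(hybrid_loss(si_terms, ec_terms, cfg0),
               hybrid_loss(si_terms, ec_terms, hybrid_config(w = 1e-8)),
               tolerance = 1e-12)
  expect_error(hybrid_config(w = 1.2), "w")
})

test_that("EC data terms are invariant to duplicating the corpus", {
  # the data-dependent EC terms (reconstruction error, latent L1) scale with
  # the image count and are normalized away by N2; the fixed weight penalties
  # are set to zero here since they do not depend on the corpus at all
  cfg <- hybrid_config(w = 0.4, ec = ec_config(alpha = 0))
  si_terms <- list(poisson = 5, l2_shared = 0.3, l2_temporal = 0.2,
                   l1_readout = 0.1, n = 10)
  ec_terms <- list(mse = 50, l2_shared = 0.3, l2_deconv = 0.2,
                   l1_latent = 3, n = 40)
  dup <- modifyList(ec_terms, list(mse = 100, l1_latent = 6, n = 80))
  expect_lt(abs(hybrid_loss(si_terms, ec_terms, cfg) -
                  hybrid_loss(si_terms, dup, cfg)), 1e-10)
})

test_that("training is reproducible and early stopping respects its contract", {
  td <- tiny_dataset()
  corpus <- generate_structured_images(24, 12, 12, 1, 0.8, seed = 3)
  cfg <- tiny_hybrid_config(w = 0.5, max_epochs = 4, patience = 2)
  m1 <- train_model(td$data, corpus, cfg, seed = 5)
  m2 <- train_model(td$data, corpus, cfg, seed = 5)
  expect_equal(m1$history, m2$history)
  expect_identical(m1$shared$W_s, m2$shared$W_s)
  expect_identical(m1$si$W_f, m2$si$W_f)
  m3 <- train_model(td$data, corpus, cfg, seed = 6)
  expect_false(identical(m1$shared$W_s, m3$shared$W_s))
  expect_lte(m1$stopped_epoch, cfg$max_epochs)
  expect_gte(m1$best_val, max(m1$history$val_metric) - 1e-12)
  # the restored snapshot reproduces the best validation metric
  ns <- asNamespace("hybridsi")
  vp <- ns$si_predict(m1$si, cfg$si, ns$stim_cache(td$data$stimulus),
                      td$data$responses$stim_split$val)
  expect_equal(ns$mean_cc(vp, td$data$responses$val_traces), m1$best_val,
               tolerance = 1e-10)
})

test_that("training the hybrid model moves one shared filter tensor, not copies", {
  td <- tiny_dataset()
  corpus <- generate_structured_images(24, 12, 12, 1, 0.8, seed = 4)
  cfg <- tiny_hybrid_config(w = 0.5, max_epochs = 1)
  m <- train_model(td$data, corpus, cfg, seed = 1)
  expect_identical(m$si$shared, m$ec$shared)
  expect_identical(m$shared, m$si$shared)
})

test_that("learning rate doubles when training on a data fraction", {
  td <- tiny_dataset(n_frames = 400)
  # one mini-batch = one Adam step per epoch; at step 1 every coordinate with
  # a nonzero gradient moves by almost exactly the learning rate
  mk <- function(frac) tiny_hybrid_config(w = 1, max_epochs = 1,
                                          data_fraction = frac,
                                          batch_si = 200)
  step_size <- function(frac) {
    m <- train_model(td$data, NULL, mk(frac), seed = 2)
    n_used <- floor(ncol(td$data$responses$train_traces) * frac)
    used <- td$data$responses$train_traces[, 4:n_used]  # clips need 4 lags
    b0 <- log(mean(used) + 1e-6)
    median(abs(m$si$b_f - b0))
  }
  lr <- mk(1)$learning_rate
  expect_equal(step_size(1), lr, tolerance = 0.05)
  expect_equal(step_size(0.9), 2 * lr, tolerance = 0.05)
})

test_that("at w = 1 hybrid training collapses to the stand-alone SI path", {
  td <- tiny_dataset()
  corpus <- generate_structured_images(24, 12, 12, 1, 0.8, seed = 4)
  cfg <- tiny_hybrid_config(w = 1, max_epochs = 2)
  m_with <- train_model(td$data, corpus, cfg, seed = 3)
  m_without <- train_model(td$data, NULL, cfg, seed = 3)
  expect_equal(m_with$shared$W_s, m_without$shared$W_s, tolerance = 1e-12)
  expect_null(m_with$ec)
})

test_that("sweep mechanics: single cell, and argmax selection over w", {
  td <- tiny_dataset()
  corpus <- generate_structured_images(24, 12, 12, 1, 0.8, seed = 5)
  cfg <- tiny_hybrid_config(max_epochs = 1)
  sw1 <- sweep_hyperparameter("w", 0.5, cfg, td$data, corpus, seeds = 1)
  expect_equal(nrow(sw1$table), 1)
  expect_equal(sw1$selected, 0.5)
  sw <- sweep_hyperparameter("w", c(0.3, 1), cfg, td$data, corpus, seeds = 1)
  expect_equal(sw$selected,
               sw$table$value[which.max(sw$table$mean_val)])
  # basis sweep over DCT counts trains basis-constrained stand-alone models
  swb <- sweep_hyperparameter("n_bases", c(1, 4), cfg, td$data,
                              seeds = 1, basis_kind = "dct")
  expect_equal(nrow(swb$table), 2)
  expect_true(swb$selected %in% c(1, 4))
  expect_error(sweep_hyperparameter("w", numeric(0), cfg, td$data, corpus),
               "nonempty")
})

test_that("training aborts with a diagnostic on divergence", {
  td <- tiny_dataset()
  cfg <- tiny_hybrid_config(w = 1, max_epochs = 1)
  cfg$learning_rate <- 1e10   # guaranteed blow-up
  expect_error(train_model(td$data, NULL, cfg, seed = 1),
               "diverged|finite")
})
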