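test_that("same-padded encoder flattens 28x28 input to 12544", {
  cfg <- ec_config(latent_dim = 32)
  p <- ec_init(cfg, 28, 28, 2, seed = 1)
  expect_equal(attr(p, "geometry")$nflat, 16 * 28 * 28)
  expect_equal(dim(p$W_e), c(32, 12544))
  x <- array(runif(2 * 28 * 28, -1, 1), c(2, 28, 28))
  out <- ec_forward(p, cfg, x)
  expect_equal(dim(out$reconstruction), c(1, 2, 28, 28))
  expect_equal(nrow(out$latent), 32)
})

test_that("evaluation passes are deterministic, training noise is not", {
  cfg <- ec_config(n_filters = 4, kernel_size = 5, latent_dim = 12,
                   noise_sd = 0.3)
  p <- ec_init(cfg, 14, 14, 2, seed = 2)
  x <- array(runif(3 * 2 * 14 * 14, -1, 1), c(3, 2, 14, 14))
  a <- ec_forward(p, cfg, x, training = FALSE)
  b <- ec_forward(p, cfg, x, training = FALSE)
  expect_identical(a$reconstruction, b$reconstruction)
  tr1 <- ec_forward(p, cfg, x, training = TRUE, seed = 1)
  tr2 <- ec_forward(p, cfg, x, training = TRUE, seed = 2)
  expect_false(identical(tr1$reconstruction, tr2$reconstruction))
  # same seed restores determinism under noise
  tr1b <- ec_forward(p, cfg, x, training = TRUE, seed = 1)
  expect_identical(tr1$reconstruction, tr1b$reconstruction)
})

test_that("reconstructions respect the tanh range and latents the ReLU sign", {
  cfg <- ec_config(n_filters = 4, kernel_size = 5, latent_dim = 12)
  p <- ec_init(cfg, 14, 14, 2, seed = 3)
  # inflate weights: output still strictly inside (-1, 1)
  p$W_dec <- p$W_dec * 3
  x <- array(runif(4 * 2 * 14 * 14, -1, 1), c(4, 2, 14, 14))
  out <- ec_forward(p, cfg, x)
  expect_lt(max(abs(out$reconstruction)), 1)
  expect_gte(min(out$latent), 0)
  expect_error(ec_forward(p, cfg, x * 3), "\\[-1, 1\\]")
})

test_that("the loss matches a brute-force oracle and its trivial cases", {
  set.seed(5)
  cfg <- ec_config(n_filters = 4, kernel_size = 5, latent_dim = 12,
                   alpha = 1.0, beta = 1.0)
  p <- ec_init(cfg, 14, 14, 2, seed = 4)
  x <- array(runif(2 * 2 * 14 * 14, -1, 1), c(2, 2, 14, 14))
  out <- ec_forward(p, cfg, x)
  got <- ec_loss(x, out$reconstruction, out$latent, p, cfg)
  want <- ec_loss_bruteforce(x, out$reconstruction, out$latent,
                             p$shared$W_s, p$W_dec, 1.0, 1.0)
  expect_lt(abs(got - want) / abs(want), 1e-10)
  # perfect reconstruction, zero penalties -> 0
  cfg0 <- ec_config(n_filters = 4, kernel_size = 5, latent_dim = 12,
                    alpha = 0, beta = 0)
  expect_equal(ec_loss(x, x, out$latent, p, cfg0), 0)
  # ReLU nonnegativity makes the L1 a plain sum
  expect_equal(sum(abs(out$latent)), sum(out$latent))
})

test_that("clip targets implement past encoding and future prediction", {
  mov <- generate_binary_noise(8, 8, 100, 2, 5, seed = 6)
  past <- make_clip_targets(mov, "past3d")
  expect_equal(dim(past$inputs), c(93, 2, 8, 8, 8))   # 100 - 8 + 1 windows
  expect_equal(dim(past$targets), c(93, 2, 8, 8))
  # past target is the 7th frame of the window
  expect_equal(past$targets[5, , , ], mov$frames[5 + 6, , , ])
  expect_equal(past$inputs[5, , 3, , ], mov$frames[5 + 2, , , ])
  fut <- make_clip_targets(mov, "future3d")
  # future target is the unseen 8th frame; 8th input slot is the mean frame
  expect_equal(fut$targets[5, , , ], mov$frames[5 + 7, , , ])
  expect_equal(fut$inputs[5, , 8, , ],
               apply(mov$frames[5:(5 + 6), , , ], c(2, 3, 4), mean))
  # minimal window and constant-movie invariance
  short <- stimulus_movie(mov$frames[1:8, , , , drop = FALSE], 5)
  expect_equal(dim(make_clip_targets(short, "past3d")$inputs)[1], 1)
  cm <- stimulus_movie(array(0.3, c(9, 2, 8, 8)), 5)
  fc <- make_clip_targets(cm, "future3d")
  expect_equal(unique(as.vector(fc$inputs)), 0.3)
  expect_equal(unique(as.vector(fc$targets)), 0.3)
  expect_error(make_clip_targets(stimulus_movie(mov$frames[1:5, , , ,
                                                           drop = FALSE], 5),
                                 "past3d"), "at least")
})

test_that("branches coupled through the shared environment see each other's updates", {
  sicfg <- si_config(n_filters = 4, kernel_size = 5, n_lags = 3)
  eccfg <- ec_config(n_filters = 4, kernel_size = 5, latent_dim = 8)
  si <- si_init(sicfg, 2, 14, 14, 2, seed = 1)
  ec <- ec_init(eccfg, 14, 14, 2, seed = 2, shared = si$shared)
  expect_identical(si$shared, ec$shared)     # same environment object
  old <- ec$shared$W_s[1, 1, 1, 1]
  si$shared$W_s[1, 1, 1, 1] <- old + 5
  expect_equal(ec$shared$W_s[1, 1, 1, 1], old + 5)
})

test_that("a trained autoencoder reconstructs held-out images better than an untrained one", {
  corpus <- generate_structured_images(80, 12, 12, 1.0, 0.8, seed = 7)
  held <- generate_structured_images(10, 12, 12, 1.0, 0.8, seed = 8)
  stim <- generate_binary_noise(12, 12, 260, 2, 5, seed = 9)
  sim <- simulate_ln_population(3, stim, rf_params = list(n_lags = 4),
                                n_test_repeats = 2, test_frames = 20,
                                seed = 10)
  cfg <- hybrid_config(w = 0,
                       si = si_config(n_filters = 4, kernel_size = 5,
                                      n_lags = 4),
                       ec = ec_config(n_filters = 4, kernel_size = 5,
                                      latent_dim = 32, alpha = 1, beta = 0.01),
                       max_epochs = 12, patience = 12, batch_ec = 16)
  m <- train_model(list(stimulus = stim, responses = sim$responses),
                   corpus, cfg, seed = 1)
  untrained <- ec_init(cfg$ec, 12, 12, 2, seed = 99)
  mse_of <- function(p) ec_forward(p, cfg$ec, held$images)$mse
  expect_lt(mse_of(m$ec), mse_of(untrained))
})
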