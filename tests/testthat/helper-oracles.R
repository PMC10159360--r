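# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths: convolutions are written as explicit loops,
# spectra via direct periodograms, losses as elementwise sums.

# Radially averaged log-amplitude slope of an image set [n, C, H, W].
radial_slope <- function(images) {
  d <- dim(images)
  h <- d[3]; w <- d[4]
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[seq_len(h)] / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[seq_len(w)] / w
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amps <- matrix(0, d[1] * d[2], length(f))
  k <- 1
  for (i in seq_len(d[1])) for (c in seq_len(d[2])) {
    amps[k, ] <- as.vector(Mod(fft(matrix(images[i, c, , ], h, w))))
    k <- k + 1
  }
  mean_amp <- colMeans(amps)
  keep <- f > 0.05 & f < 0.45
  bins <- cut(log(f[keep]), breaks = 12)
  lf <- tapply(log(f[keep]), bins, mean)
  la <- tapply(log(mean_amp[keep]), bins, mean)
  ok <- is.finite(lf) & is.finite(la)
  unname(coef(lm(la[ok] ~ lf[ok]))[2])
}

excess_kurtosis <- function(x) {
  x <- as.vector(x)
  mean((x - mean(x))^4) / stats::var(x)^2 - 3
}

# Direct (loop-based) valid 2D convolution of a [C, H, W] image with a
# [C, K, K] kernel; returns the [OH, OW] feature map.
conv2d_valid_loop <- function(img, kern) {
  C <- dim(img)[1]; H <- dim(img)[2]; W <- dim(img)[3]
  K <- dim(kern)[2]
  OH <- H - K + 1; OW <- W - K + 1
  out <- matrix(0, OH, OW)
  for (oy in seq_len(OH)) for (ox in seq_len(OW)) {
    s <- 0
    for (c in seq_len(C))
      s <- s + sum(img[c, oy:(oy + K - 1), ox:(ox + K - 1)] * kern[c, , ])
    out[oy, ox] <- s
  }
  out
}

# Brute-force Poisson loss with penalties (2D factorized form).
si_loss_bruteforce <- function(pred, target, Ws, Wt, Wf, a1, a2, b) {
  s <- 0
  for (i in seq_along(pred))
    s <- s + pred[i] - if (target[i] > 0) target[i] * log(pred[i]) else 0
  s + a1 * sum(Ws^2) + a2 * sum(Wt^2) + b * sum(abs(Wf))
}

ec_loss_bruteforce <- function(x, xhat, h, Wc, Wd, a, b) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - xhat[i])^2
  s + a * (sum(Wc^2) + sum(Wd^2)) + b * sum(abs(h))
}

# Eqs for the weighted hybrid objective, written out directly.
hybrid_loss_bruteforce <- function(w, poisson, l2s, l2t, l1f, n1,
                                   mse, l2d, l1h, n2, a1, a2, b1, a3, b2) {
  we <- min(max(w, 1e-8), 1 - 1e-8)
  lsi <- (poisson + a1 * l2s + a2 * l2t / we + b1 * l1f / we) / n1
  lec <- (mse + a3 * l2s + a3 * l2d / (1 - we) + b2 * l1h / (1 - we)) / n2
  we * lsi + (1 - we) * lec
}

# Small shared fixtures ------------------------------------------------------

tiny_geometry <- function() {
  list(H = 12, W = 12, K = 5, nf = 3, L = 4, C = 2, N = 4)
}

tiny_dataset <- function(n_neurons = 6, n_frames = 260, seed = 7) {
  stim <- generate_binary_noise(12, 12, n_frames, 2, 5, seed = seed)
  sim <- simulate_ln_population(n_neurons, stim,
                                rf_params = list(sigma_center = c(1, 1.5),
                                                 n_lags = 4),
                                n_test_repeats = 3, test_frames = 20,
                                seed = seed + 1)
  list(data = list(stimulus = stim, responses = sim$responses),
       neurons = sim$neurons)
}

tiny_hybrid_config <- function(w = 0.5, max_epochs = 2, batch_si = 16,
                               batch_ec = 8, ...) {
  hybrid_config(w = w,
                si = si_config(n_filters = 3, kernel_size = 5, n_lags = 4),
                ec = ec_config(n_filters = 3, kernel_size = 5,
                               latent_dim = 16, n_lags = 4),
                batch_si = batch_si, batch_ec = batch_ec,
                max_epochs = max_epochs, ...)
}
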