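#' Efficient-coding autoencoder configuration
#'
#' A convolutional autoencoder without a classical unit bottleneck: bandwidth
#' is limited by Gaussian noise on the encoder output and an L1 penalty on
#' its activation. The encoder is a single same-padded convolution -> ReLU ->
#' fully connected layer -> ReLU; the decoder mirrors it with a fully
#' connected layer -> ReLU -> transposed convolution -> tanh, mapping back to
#' the stimulus range `[-1, 1]`. In `past3d` mode the input is an 8-frame
#' clip and the target its 7th frame; in `future3d` the input is the first 7
#' frames (8th slot filled with their per-channel mean) and the target the
#' 8th frame.
#'
#' @param n_filters number of convolutional filters (default 16).
#' @param kernel_size kernel side length (default 9; same padding of
#'   `(kernel_size - 1)/2`).
#' @param latent_dim size of the encoder output (default 512).
#' @param noise_sd SD of the Gaussian noise added to the encoder output
#'   during training (default 0.1, in units of post-ReLU activation; off at
#'   evaluation).
#' @param alpha L2 penalty weight on conv and deconv filters (default 1000).
#' @param beta L1 penalty weight on the encoder activation (default 1/16).
#' @param n_lags clip length for the 3D modes (default 8).
#' @param mode `"image2d"`, `"past3d"` or `"future3d"`.
#' @return An object of class `ec_config`.
#' @export
ec_config <- function(n_filters = 16, kernel_size = 9, latent_dim = 512,
                      noise_sd = 0.1, alpha = 1000, beta = 1 / 16,
                      n_lags = 8, mode = c("image2d", "past3d", "future3d")) {
  mode <- match.arg(mode)
  if (kernel_size %% 2 != 1) stop("`kernel_size` must be odd (same padding)")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(alpha, "alpha", lower = 0)
  check_scalar(beta, "beta", lower = 0)
  structure(list(n_filters = check_count(n_filters, "n_filters"),
                 kernel_size = check_count(kernel_size, "kernel_size"),
                 latent_dim = check_count(latent_dim, "latent_dim"),
                 noise_sd = noise_sd, alpha = alpha, beta = beta,
                 n_lags = check_count(n_lags, "n_lags"), mode = mode),
            class = "ec_config")
}

#' Initialize autoencoder parameters
#'
#' Creates the EC parameter environment. Pass the SI branch's `shared`
#' environment to couple the branches: the convolutional filter tensor is
#' then the identical parameter object in both branches, not a copy.
#'
#' @param config an [ec_config].
#' @param in_height,in_width input image size in pixels.
#' @param n_channels number of chromatic channels.
#' @param seed integer seed.
#' @param shared optional existing shared-filter environment.
#' @return A parameter environment with a `geometry` attribute.
#' @export
ec_init <- function(config, in_height, in_width, n_channels = 2, seed = 1,
                    shared = NULL) {
  stopifnot(inherits(config, "ec_config"))
  nf <- config$n_filters; K <- config$kernel_size
  npix <- in_height * in_width
  nflat <- nf * npix
  ld <- config$latent_dim
  pars <- local_seed(seed, {
    e <- new.env(parent = emptyenv())
    if (is.null(shared)) {
      shared <- new.env(parent = emptyenv())
      if (config$mode == "image2d") {
        shared$W_s <- array(rnorm(nf * n_channels * K * K,
                                  sd = sqrt(1 / (n_channels * K * K))),
                            c(nf, n_channels, K, K))
      } else {
        L <- config$n_lags
        shared$W_c <- array(rnorm(nf * n_channels * L * K * K,
                                  sd = sqrt(1 / (n_channels * L * K * K))),
                            c(nf, n_channels, L, K, K))
      }
    }
    e$shared <- shared
    e$b_c <- rep(0, nf)
    e$W_e <- matrix(rnorm(ld * nflat, sd = sqrt(1 / nflat)), ld, nflat)
    e$b_e <- rep(0, ld)
    e$W_dfc <- matrix(rnorm(nflat * ld, sd = sqrt(1 / ld)), nflat, ld)
    e$b_dfc <- rep(0, nflat)
    e$W_dec <- array(rnorm(nf * n_channels * K * K,
                           sd = sqrt(1 / (nf * K * K))),
                     c(nf, n_channels, K, K))
    e$b_dec <- rep(0, n_channels)
    e
  })
  attr(pars, "geometry") <- list(H = in_height, W = in_width, C = n_channels,
                                 npix = npix, nflat = nflat)
  pars
}

# Forward (and optional backward) pass of the autoencoder.
#
# x:       (H, W, C, B) images in image2d mode, (H, W, C, L, B) clips in the
#          3D modes (already containing the mean-filled 8th slot for future3d)
# target:  (H, W, C, B); defaults to x in image2d mode
# noise:   add encoder noise (training) or not (evaluation)
# scales:  list(mse, l1) upstream gradient scales; gradients are returned
#          when `backward = TRUE`
ec_step <- function(pars, config, x, target = NULL, noise = TRUE,
                    backward = FALSE, scales = list(mse = 1, l1 = 0)) {
  geom <- attr(pars, "geometry")
  nf <- config$n_filters; K <- config$kernel_size
  pad <- (K - 1) %/% 2
  H <- geom$H; W <- geom$W; C <- geom$C; npix <- geom$npix
  if (config$mode == "image2d") {
    d <- dim(x); B <- d[4]
    if (is.null(target)) target <- x
    P <- im2col_pooled(x, K, pad, "ec_enc")                 # (K2C x npix*B)
    Wmat <- ws_to_mat(pars$shared$W_s)
    A1 <- Wmat %*% P + pars$b_c
  } else {
    d <- dim(x); L <- d[4]; B <- d[5]
    if (L != config$n_lags) stop("clip length does not match `n_lags`")
    if (is.null(target)) stop("3D modes need an explicit target frame")
    xf <- x
    dim(xf) <- c(H, W, C, L * B)
    P <- im2col(xf, K, pad)                                 # (K2C x npix*L*B)
    dim(P) <- c(K * K * C, npix, L, B)
    P <- aperm(P, c(1, 3, 2, 4))                            # rows (ky,kx,c | lag)
    dim(P) <- c(K * K * C * L, npix * B)
    Wmat <- w3_to_mat(pars$shared$W_c)
    A1 <- Wmat %*% P + pars$b_c
  }
  M1 <- A1 > 0
  H1 <- A1 * M1                                             # (nf x npix*B)
  H0 <- H1
  dim(H0) <- c(geom$nflat, B)
  Ze <- pars$W_e %*% H0 + pars$b_e
  Hl <- Ze * (Ze > 0)                                       # encoder output
  Hn <- if (noise && config$noise_sd > 0)
    Hl + matrix(rnorm(length(Hl), sd = config$noise_sd), nrow(Hl), ncol(Hl))
  else Hl
  Zd <- pars$W_dfc %*% Hn + pars$b_dfc
  D <- Zd * (Zd > 0)
  dim(D) <- c(nf, npix * B)
  Wdm <- ws_to_mat(pars$W_dec)                              # (nf x K2C)
  Pout <- crossprod(Wdm, D)                                 # (K2C x npix*B)
  buf <- col2im_pooled(Pout, H, W, C, B, K, pad, "ec_img")
  Tpre <- buf + rep(rep(pars$b_dec, each = H * W), times = B)
  dim(Tpre) <- c(H, W, C, B)
  xhat <- tanh(Tpre)
  res <- xhat - target
  out <- list(xhat = xhat, h = Hl, mse = sum(res * res), l1h = sum(Hl))

  if (backward) {
    dT <- (2 * scales$mse * res) * (1 - xhat * xhat)
    gb_dec <- apply(dT, 3, sum)
    dP_out <- if (config$mode == "image2d") im2col_pooled(dT, K, pad, "ec_dec")
              else im2col(dT, K, pad)                       # (K2C x npix*B)
    gW_dec <- mat_to_ws(tcrossprod(D, dP_out), nf, C, K)
    dD <- Wdm %*% dP_out                                    # (nf x npix*B)
    dim(dD) <- c(geom$nflat, B)
    dZd <- dD * (Zd > 0)
    g <- list(W_dec = gW_dec, b_dec = gb_dec,
              W_dfc = tcrossprod(dZd, Hn), b_dfc = rowSums(dZd))
    dHn <- crossprod(pars$W_dfc, dZd)
    dHl <- dHn + scales$l1 * (Hl > 0)
    dZe <- dHl * (Ze > 0)
    g$W_e <- tcrossprod(dZe, H0)
    g$b_e <- rowSums(dZe)
    dH0 <- crossprod(pars$W_e, dZe)
    dim(dH0) <- c(nf, npix * B)
    dA1 <- dH0 * M1
    g$b_c <- rowSums(dA1)
    gWmat <- tcrossprod(dA1, P)
    if (config$mode == "image2d") {
      g$W_s <- mat_to_ws(gWmat, nf, C, K)
    } else {
      g$W_c <- mat_to_w3(gWmat, nf, C, config$n_lags, K)
    }
    out$grads <- g
  }
  out
}

#' Forward pass of the autoencoder branch
#'
#' Encodes and reconstructs a batch of images (2D mode) or movie clips (3D
#' modes). During training (`training = TRUE`) Gaussian noise of SD
#' `config$noise_sd` is added to the encoder output; at evaluation the pass
#' is deterministic.
#'
#' @param params parameter environment from [ec_init].
#' @param config an [ec_config].
#' @param x array `[n x channel x H x W]` (2D) or `[n x channel x n_lags x H
#'   x W]` (3D), values in `[-1, 1]`; a single image/clip without the leading
#'   `n` is also accepted.
#' @param training whether to inject encoder noise.
#' @param seed seed for the noise draw.
#' @return List with `reconstruction` (same layout as a frame batch
#'   `[n x channel x H x W]`, values in `(-1, 1)`) and `latent`
#'   `[latent_dim x n]`.
#' @export
ec_forward <- function(params, config, x, training = FALSE, seed = 1) {
  d <- dim(x)
  nd <- if (config$mode == "image2d") 4L else 5L
  if (length(d) == nd - 1L) {
    x <- array(x, c(1, d)); d <- dim(x)
  }
  if (length(d) != nd) stop("input has the wrong number of dimensions")
  if (max(abs(x)) > 1 + 1e-12) stop("input values must lie in [-1, 1]")
  if (config$mode == "image2d") {
    xi <- aperm(x, c(3, 4, 2, 1))                           # (H,W,C,B)
    target <- NULL
  } else {
    xi <- aperm(x, c(4, 5, 2, 3, 1))                        # (H,W,C,L,B)
    tgt_idx <- if (config$mode == "past3d") d[3] - 1L else d[3]
    target <- xi[, , , tgt_idx, , drop = TRUE]
    dim(target) <- dim(xi)[c(1, 2, 3, 5)]
  }
  res <- local_seed(seed, ec_step(params, config, xi, target = target,
                                  noise = training, backward = FALSE))
  list(reconstruction = aperm(res$xhat, c(4, 3, 1, 2)),
       latent = res$h, mse = res$mse)
}

#' Autoencoder loss
#'
#' Reconstruction mean-squared-error term plus penalties:
#' `sum((x - xhat)^2) + alpha * (||w_c||^2 + ||w_d||^2) + beta * ||h||_1`.
#'
#' @param x,xhat target and reconstruction, same shape.
#' @param h encoder activation (nonnegative, post-ReLU).
#' @param params parameter environment from [ec_init].
#' @param config an [ec_config].
#' @return A finite scalar.
#' @export
ec_loss <- function(x, xhat, h, params, config) {
  if (!identical(dim(x), dim(xhat))) stop("`x` and `xhat` shapes differ")
  conv <- if (config$mode == "image2d") params$shared$W_s else params$shared$W_c
  out <- sum((x - xhat)^2) +
    config$alpha * (l2sq(conv) + l2sq(params$W_dec)) +
    config$beta * l1(h)
  if (!is.finite(out)) stop("loss is not finite")
  out
}

#' Clip inputs and frame targets for the 3D autoencoder
#'
#' Slides an `n_lags`-frame window (stride 1) over a movie. In `past3d` mode
#' the target of the window ending at frame `t` is the frame at `t - 1`; in
#' `future3d` mode the last input slot is replaced by the per-channel mean of
#' the first `n_lags - 1` frames and the target is the final (unseen) frame.
#'
#' @param movie a [stimulus_movie] with at least `n_lags` frames.
#' @param mode `"past3d"` or `"future3d"`.
#' @param n_lags clip length (default 8).
#' @return List with `inputs` `[n x channel x n_lags x H x W]` and `targets`
#'   `[n x channel x H x W]`, where `n = n_frames - n_lags + 1`.
#' @export
make_clip_targets <- function(movie, mode = c("past3d", "future3d"),
                              n_lags = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  L <- check_count(n_lags, "n_lags")
  if (d[1] < L) stop(sprintf("movie must have at least %d frames", L))
  n <- d[1] - L + 1
  inputs <- array(0, c(n, d[2], L, d[3], d[4]))
  targets <- array(0, c(n, d[2], d[3], d[4]))
  for (i in seq_len(n)) {
    win <- movie$frames[i:(i + L - 1), , , , drop = FALSE]  # [L,C,H,W]
    if (mode == "past3d") {
      inputs[i, , , , ] <- aperm(win, c(2, 1, 3, 4))
      targets[i, , , ] <- win[L - 1, , , ]
    } else {
      filled <- win
      filled[L, , , ] <- apply(win[seq_len(L - 1), , , , drop = FALSE],
                               c(2, 3, 4), mean)
      inputs[i, , , , ] <- aperm(filled, c(2, 1, 3, 4))
      targets[i, , , ] <- win[L, , , ]
    }
  }
  list(inputs = inputs, targets = targets)
}
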