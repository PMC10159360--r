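#' System-identification model configuration
#'
#' Architecture and regularization settings for the convolutional encoding
#' model. In `factorized2d` mode the model applies one spatial convolutional
#' layer (no padding), one temporal convolutional layer collapsing the
#' stimulus lags, and a fully connected readout followed by an exponential
#' output nonlinearity; the loss is the Poisson negative log-likelihood plus
#' an L2 penalty on the spatial filters (`alpha1`), an L2 penalty on the
#' temporal filters (`alpha2`) and an L1 penalty on the readout (`beta`). In
#' `spatiotemporal3d` mode a single joint space-time convolution replaces the
#' factorized pair and `alpha1` penalizes the joint filters (`alpha2` is
#' unused).
#'
#' @param n_filters number of convolutional filters (default 16).
#' @param kernel_size spatial kernel side length (default 9).
#' @param n_lags stimulus frames preceding a response sample (8 for 5-Hz
#'   noise, 30 for 30-Hz noise, 50 for movies).
#' @param mode `"factorized2d"` or `"spatiotemporal3d"`.
#' @param alpha1,alpha2,beta penalty weights (all >= 0). Defaults follow the
#'   grid-search optima for the two modes: `(10, 10, 1/16)` for factorized,
#'   `(100, -, 1/4)` for joint filters.
#' @param basis optional [basis_set]; when given, the spatial filters are
#'   composed from the basis and only the composition weights are learned.
#' @return An object of class `si_config`.
#' @export
si_config <- function(n_filters = 16, kernel_size = 9, n_lags = 8,
                      mode = c("factorized2d", "spatiotemporal3d"),
                      alpha1 = NULL, alpha2 = NULL, beta = NULL,
                      basis = NULL) {
  mode <- match.arg(mode)
  if (is.null(alpha1)) alpha1 <- if (mode == "factorized2d") 10 else 100
  if (is.null(alpha2)) alpha2 <- 10
  if (is.null(beta)) beta <- if (mode == "factorized2d") 1 / 16 else 1 / 4
  check_scalar(alpha1, "alpha1", lower = 0)
  check_scalar(alpha2, "alpha2", lower = 0)
  check_scalar(beta, "beta", lower = 0)
  if (!is.null(basis) && mode != "factorized2d")
    stop("basis-constrained filters are supported for the factorized model")
  structure(list(n_filters = check_count(n_filters, "n_filters"),
                 kernel_size = check_count(kernel_size, "kernel_size"),
                 n_lags = check_count(n_lags, "n_lags"),
                 mode = mode, alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                 basis = basis),
            class = "si_config")
}

#' Initialize system-identification parameters
#'
#' Creates the SI parameter environment: the shareable spatial (or joint
#' spatio-temporal) convolutional filter tensor lives in a nested `shared`
#' environment, so that passing the same `shared` environment to the
#' autoencoder branch couples the two branches through one parameter object
#' (not a copy). The readout is initialized near zero so the initial
#' prediction is close to `exp(b_f)`.
#'
#' @param config an [si_config].
#' @param n_neurons number of readout neurons.
#' @param in_height,in_width input frame size in pixels.
#' @param n_channels number of chromatic channels.
#' @param seed integer seed.
#' @param shared optional existing shared-filter environment.
#' @return A parameter environment with a `geometry` attribute.
#' @export
si_init <- function(config, n_neurons, in_height, in_width, n_channels = 2,
                    seed = 1, shared = NULL) {
  stopifnot(inherits(config, "si_config"))
  nf <- config$n_filters; K <- config$kernel_size; L <- config$n_lags
  oh <- in_height - K + 1; ow <- in_width - K + 1
  if (oh < 1 || ow < 1) stop("input smaller than the convolution kernel")
  nflat <- nf * oh * ow
  pars <- local_seed(seed, {
    e <- new.env(parent = emptyenv())
    if (is.null(shared)) {
      shared <- new.env(parent = emptyenv())
      if (!is.null(config$basis)) {
        k <- config$basis$k
        if (config$basis$kind == "pca") {
          shared$basis_weights <- matrix(rnorm(nf * k, sd = sqrt(1 / k)), nf, k)
        } else {
          shared$basis_weights <-
            array(rnorm(nf * k * n_channels, sd = sqrt(1 / k)),
                  c(nf, k, n_channels))
        }
      } else if (config$mode == "factorized2d") {
        shared$W_s <- array(rnorm(nf * n_channels * K * K,
                                  sd = sqrt(1 / (n_channels * K * K))),
                            c(nf, n_channels, K, K))
      } else {
        shared$W_c <- array(rnorm(nf * n_channels * L * K * K,
                                  sd = sqrt(1 / (n_channels * L * K * K))),
                            c(nf, n_channels, L, K, K))
      }
    }
    e$shared <- shared
    if (config$mode == "factorized2d")
      e$W_t <- array(rnorm(nf * nf * L, sd = sqrt(1 / (nf * L))), c(nf, nf, L))
    e$W_f <- matrix(rnorm(n_neurons * nflat, sd = 1e-3), n_neurons, nflat)
    e$b_f <- rep(0, n_neurons)
    e
  })
  attr(pars, "geometry") <- list(n_neurons = n_neurons, H = in_height,
                                 W = in_width, C = n_channels,
                                 OH = oh, OW = ow, nflat = nflat)
  pars
}

# Current spatial (2D) filter tensor [nf, C, K, K], composing from the basis
# when the model is basis-constrained.
si_spatial_filters <- function(pars, config, n_channels) {
  if (!is.null(config$basis))
    compose_filters_from_basis(pars$shared$basis_weights, config$basis,
                               n_channels = n_channels)
  else pars$shared$W_s
}

# Forward (and optional backward) pass over a batch of time points.
#
# cache:  stim_cache() of the stimulus movie
# t_idx:   time indices (all >= n_lags)
# dZ:      upstream gradient w.r.t. the log-rate [n_neurons x B]; when given,
#          gradients for all SI parameters are returned.
# targets: alternatively, observed rates [n_neurons x B]; the Poisson
#          gradient (pred - targets) * dscale is then used as dZ.
si_step <- function(pars, config, cache, t_idx, dZ = NULL, targets = NULL,
                    dscale = 1, want_input_grad = FALSE) {
  geom <- attr(pars, "geometry")
  nf <- config$n_filters; K <- config$kernel_size; L <- config$n_lags
  C <- cache$C; H <- cache$H; Wd <- cache$W
  B <- length(t_idx)
  if (any(t_idx < L) || any(t_idx > cache$T))
    stop("time indices must lie in [n_lags, n_frames]")
  npos <- geom$OH * geom$OW
  umat <- matrix(rep(t_idx, each = L) + ((1:L) - L), L, B)  # frames per clip
  u <- sort(unique(as.vector(umat)))
  pos <- matrix(match(umat, u), L, B)
  nu <- length(u)
  P <- if (config$mode == "factorized2d")
    im2col_pooled(cache$x[, , , u, drop = FALSE], K, 0L, "si")
  else im2col(cache$x[, , , u, drop = FALSE], K, 0L)        # (K2C x npos*nu)

  if (config$mode == "factorized2d") {
    Wmat <- ws_to_mat(si_spatial_filters(pars, config, C))
    S <- Wmat %*% P                                         # (nf x npos*nu)
    dim(S) <- c(nf, npos, nu)
    G <- S[, , as.vector(pos), drop = FALSE]                # (nf,npos,L*B)
    dim(G) <- c(nf, npos, L, B)
    G <- aperm(G, c(1, 3, 2, 4))                            # (nf,L,npos,B)
    dim(G) <- c(nf * L, npos * B)
    Wt_mat <- matrix(pars$W_t, nrow = nf)
    Fm <- Wt_mat %*% G                                      # (nf x npos*B)
  } else {
    dim(P) <- c(K * K * C, npos, nu)
    P3 <- P[, , as.vector(pos), drop = FALSE]
    dim(P3) <- c(K * K * C, npos, L, B)
    P3 <- aperm(P3, c(1, 3, 2, 4))                          # rows (ky,kx,c | lag)
    dim(P3) <- c(K * K * C * L, npos * B)
    W3m <- w3_to_mat(pars$shared$W_c)
    Fm <- W3m %*% P3
  }
  Fmat <- Fm
  dim(Fmat) <- c(nf * npos, B)
  Z <- pars$W_f %*% Fmat + pars$b_f
  pred <- exp(Z)
  out <- list(Z = Z, pred = pred)
  if (is.null(dZ) && !is.null(targets)) dZ <- (pred - targets) * dscale

  if (!is.null(dZ)) {
    g <- list(W_f = tcrossprod(dZ, Fmat), b_f = rowSums(dZ))
    dF <- crossprod(pars$W_f, dZ)                           # (nf*npos x B)
    dim(dF) <- c(nf, npos * B)
    if (config$mode == "factorized2d") {
      g$W_t <- array(tcrossprod(dF, G), c(nf, nf, L))
      dG <- crossprod(Wt_mat, dF)                           # (nf*L x npos*B)
      dim(dG) <- c(nf, L, npos, B)
      dS <- array(0, c(nf, npos, nu))
      for (b in seq_len(B)) for (l in seq_len(L))
        dS[, , pos[l, b]] <- dS[, , pos[l, b]] + dG[, l, , b]
      dim(dS) <- c(nf, npos * nu)
      gWmat <- tcrossprod(dS, P)
      if (!is.null(config$basis)) {
        gWs <- mat_to_ws(gWmat, nf, C, K)
        g$basis_weights <- basis_weight_grad(gWs, config$basis, C)
      } else {
        g$W_s <- mat_to_ws(gWmat, nf, C, K)
      }
      if (want_input_grad) {
        dP <- crossprod(Wmat, dS)
        g$input <- col2im(dP, H, Wd, C, nu, K, 0L)
        g$input_frames <- u
      }
    } else {
      g$W_c <- mat_to_w3(tcrossprod(dF, P3), nf, C, L, K)
      if (want_input_grad) {
        dP3 <- crossprod(W3m, dF)                           # (K2CL x npos*B)
        dim(dP3) <- c(K * K * C, L, npos, B)
        # scatter over lags back onto frames
        acc <- array(0, c(K * K * C, npos, nu))
        for (b in seq_len(B)) for (l in seq_len(L))
          acc[, , pos[l, b]] <- acc[, , pos[l, b]] + dP3[, l, , b]
        dim(acc) <- c(K * K * C, npos * nu)
        g$input <- col2im(acc, H, Wd, C, nu, K, 0L)
        g$input_frames <- u
      }
    }
    out$grads <- g
  }
  out
}

# Gradient w.r.t. basis weights from a gradient w.r.t. the composed filters.
basis_weight_grad <- function(gWs, basis, n_channels) {
  k <- basis$k
  nf <- dim(gWs)[1]
  if (basis$kind == "pca") {
    bm <- matrix(basis$basis, nrow = k)
    tcrossprod(matrix(gWs, nrow = nf), bm)
  } else {
    N <- dim(basis$basis)[2]
    bm <- matrix(basis$basis, nrow = k)
    out <- array(0, c(nf, k, n_channels))
    for (c in seq_len(n_channels))
      out[, , c] <- tcrossprod(matrix(gWs[, c, , ], nf, N * N), bm)
    out
  }
}

#' Forward pass of the system-identification model
#'
#' Predicts firing rates for one stimulus clip or a batch of clips. Rates are
#' strictly positive (exponential output).
#'
#' @param params parameter environment from [si_init] (or a
#'   [train_model] result's `$si`).
#' @param config an [si_config].
#' @param clip numeric array `[channel x n_lags x H x W]`, or a batch
#'   `[B x channel x n_lags x H x W]`.
#' @return Numeric matrix `[n_neurons x B]` of predicted rates.
#' @export
si_forward <- function(params, config, clip) {
  d <- dim(clip)
  if (length(d) == 4L) {
    clip <- array(clip, c(1, d))
    d <- dim(clip)
  }
  if (length(d) != 5L)
    stop("`clip` must be [channel x n_lags x H x W] or a batch thereof")
  B <- d[1]; C <- d[2]; L <- d[3]; H <- d[4]; W <- d[5]
  if (L != config$n_lags)
    stop(sprintf("clip has %d lags but the model expects %d", L, config$n_lags))
  geom <- attr(params, "geometry")
  if (H != geom$H || W != geom$W || C != geom$C)
    stop("clip geometry does not match the model")
  # lay the clips out as consecutive frames and point each sample at its own
  # L-frame window
  frames <- aperm(clip, c(4, 5, 2, 3, 1))       # (H, W, C, L, B)
  dim(frames) <- c(H, W, C, L * B)
  cache <- list(x = frames, T = L * B, C = C, H = H, W = W)
  si_step(params, config, cache, t_idx = seq_len(B) * L)$pred
}

#' System-identification loss
#'
#' Poisson negative log-likelihood plus the configured penalties:
#' `sum(pred - target * log(pred))` plus `alpha1 * ||w_s||^2 +
#' alpha2 * ||w_t||^2 + beta * ||w_f||_1` for factorized filters, or
#' `alpha1 * ||w_c||^2 + beta * ||w_f||_1` for joint spatio-temporal filters.
#'
#' @param pred predicted rates (positive).
#' @param target observed rates (nonnegative).
#' @param params parameter environment.
#' @param config an [si_config].
#' @return A finite scalar.
#' @export
si_loss <- function(pred, target, params, config) {
  if (any(pred <= 0) && any(target[pred <= 0] > 0))
    stop("nonpositive prediction with positive target: Poisson loss undefined")
  terms <- pred
  pos <- target > 0
  terms[pos] <- pred[pos] - target[pos] * log(pred[pos])
  data_term <- sum(terms)
  geom <- attr(params, "geometry")
  if (config$mode == "factorized2d") {
    Ws <- si_spatial_filters(params, config, geom$C)
    pen <- config$alpha1 * l2sq(Ws) + config$alpha2 * l2sq(params$W_t)
  } else {
    pen <- config$alpha1 * l2sq(params$shared$W_c)
  }
  pen <- pen + config$beta * l1(params$W_f)
  out <- data_term + pen
  if (!is.finite(out)) stop("loss is not finite")
  out
}
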