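#' Estimate a neuron's receptive field from a trained model
#'
#' Computes the gradient of the neuron's pre-exponential output (log rate)
#' with respect to the stimulus, evaluated at an all-zero input sequence --
#' the first-order approximation of the stimulus that maximally drives the
#' neuron. The spatio-temporal gradient is factorized by SVD of its
#' `[lags x pixels]` matricization (channels stacked along pixels): the
#' temporal component has unit L2 norm with its largest-magnitude lag
#' positive, and the spatial component absorbs polarity and magnitude.
#'
#' @param model a [train_model] result with an SI branch.
#' @param neuron neuron index.
#' @return An object of class `rf_estimate` with `spatiotemporal`
#'   `[channel x lag x H x W]`, `spatial_component` `[channel x H x W]`,
#'   `temporal_component` `[lags]` (unit norm) and `singular_value_ratio`
#'   (leading singular value over the sum).
#' @export
estimate_rf <- function(model, neuron) {
  if (is.null(model$si)) stop("model has no SI branch")
  si <- model$si; cfg <- model$config$si
  geom <- attr(si, "geometry")
  neuron <- check_count(neuron, "neuron")
  if (neuron > geom$n_neurons) stop("invalid neuron index")
  nf <- cfg$n_filters; K <- cfg$kernel_size; L <- cfg$n_lags
  C <- geom$C; H <- geom$H; W <- geom$W
  npos <- geom$OH * geom$OW
  G <- matrix(si$W_f[neuron, ], nf, npos)     # d(lograte)/d(feature maps)
  rf <- array(0, c(C, L, H, W))
  if (cfg$mode == "factorized2d") {
    Wmat <- ws_to_mat(si_spatial_filters(si, cfg, C))
    for (l in seq_len(L)) {
      dS <- crossprod(matrix(si$W_t[, , l], nf, nf), G)    # (nf x npos)
      dP <- crossprod(Wmat, dS)                            # (K2C x npos)
      img <- col2im(dP, H, W, C, 1L, K, 0L)                # (H,W,C,1)
      rf[, l, , ] <- aperm(img[, , , 1, drop = FALSE], c(3, 1, 2, 4))[, , , 1]
    }
  } else {
    W3m <- w3_to_mat(si$shared$W_c)
    dP3 <- crossprod(W3m, G)                               # (K2C*L x npos)
    dim(dP3) <- c(K * K * C, L, npos)
    for (l in seq_len(L)) {
      img <- col2im(dP3[, l, ], H, W, C, 1L, K, 0L)
      rf[, l, , ] <- aperm(img[, , , 1, drop = FALSE], c(3, 1, 2, 4))[, , , 1]
    }
  }
  factorize_rf(rf)
}

# SVD factorization of a [channel x lag x H x W] receptive field into one
# temporal and one spatial component.
factorize_rf <- function(rf) {
  d <- dim(rf)
  C <- d[1]; L <- d[2]; H <- d[3]; W <- d[4]
  M <- matrix(aperm(rf, c(2, 1, 3, 4)), L)      # lags x (C*H*W)
  sv <- svd(M)
  u <- sv$u[, 1]
  s <- if (u[which.max(abs(u))] < 0) -1 else 1
  temporal <- s * u
  spatial <- array(s * sv$d[1] * sv$v[, 1], c(C, H, W))
  structure(list(spatiotemporal = rf,
                 spatial_component = spatial,
                 temporal_component = temporal,
                 singular_value_ratio = sv$d[1] / sum(sv$d)),
            class = "rf_estimate")
}

#' Fit a 2D Gaussian to a spatial filter
#'
#' Least-squares fit of an elliptical Gaussian (amplitude, center, sigmas,
#' rotation, offset) to a spatial filter, quantifying how closely the filter
#' resembles the smooth, Gaussian-like receptive fields of early visual
#' neurons. The coefficient of determination is clipped to `[0, 1]` and
#' forced to 0 when the fitted sigma exceeds the filter size (the fit has
#' left the filter support). The score is invariant to sign flips and
#' rescaling of the filter.
#'
#' @param spatial_filter numeric matrix `[H x W]`.
#' @param max_sigma sigma bound in pixels above which the fit is scored 0
#'   (default: the filter size).
#' @param n_restarts jittered re-initializations of the nonlinear fit.
#' @return An object of class `gaussian_fit` with `center`, `sigmas`,
#'   `amplitude`, `offset`, `rotation` and `r_squared`.
#' @export
gaussian_fit_r2 <- function(spatial_filter, max_sigma = NULL, n_restarts = 5) {
  f <- as.matrix(spatial_filter)
  if (!all(is.finite(f))) stop("filter must be finite")
  H <- nrow(f); W <- ncol(f)
  if (is.null(max_sigma)) max_sigma <- max(H, W)
  ss_tot <- sum((f - mean(f))^2)
  empty <- structure(list(center = c(NA, NA), sigmas = c(NA, NA),
                          amplitude = NA, offset = NA, rotation = NA,
                          r_squared = 0), class = "gaussian_fit")
  if (ss_tot == 0) return(empty)
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  z <- as.vector(f)
  model_fun <- function(p) {
    dy <- grid$y - p[3]; dx <- grid$x - p[2]
    ct <- cos(p[6]); st <- sin(p[6])
    xr <- dx * ct + dy * st
    yr <- -dx * st + dy * ct
    p[7] + p[1] * exp(-0.5 * (xr^2 / p[4]^2 + yr^2 / p[5]^2))
  }
  resid_fun <- function(p) model_fun(p) - z
  pk <- which.max(abs(f))
  pky <- (pk - 1) %% H + 1; pkx <- (pk - 1) %/% H + 1
  base_init <- c(f[pk] - stats::median(f), pkx, pky, 2, 2, 0, stats::median(f))
  best <- NULL; best_ss <- Inf
  for (r in seq_len(n_restarts)) {
    init <- base_init
    if (r > 1) {
      jit <- local_seed(1000 + r, rnorm(7, sd = c(abs(base_init[1]) * 0.3 + 1e-3,
                                                  1, 1, 0.7, 0.7, 0.4, 0.05)))
      init <- base_init + jit
      init[4:5] <- pmax(abs(init[4:5]), 0.3)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = init, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(fit$fvec^2)
      if (ss < best_ss) {
        best_ss <- ss; best <- fit$par
      }
    }
  }
  if (is.null(best)) return(empty)
  sig <- abs(best[4:5])
  r2 <- 1 - best_ss / ss_tot
  r2 <- min(max(r2, 0), 1)
  if (max(sig) > max_sigma) r2 <- 0
  structure(list(center = c(x = best[2], y = best[3]),
                 sigmas = c(sx = sig[1], sy = sig[2]),
                 amplitude = best[1], offset = best[7],
                 rotation = best[6] %% pi, r_squared = r2),
            class = "gaussian_fit")
}

#' Dominant chromatic channel of a receptive field
#'
#' The chromatic channel whose spatial component has the largest peak
#' absolute value. The filter-plausibility metric is computed on this channel
#' only, mirroring the dominance of the green channel in dorsal retina and of
#' the UV channel in ventral retina. Exact ties resolve to the lower index
#' (with a message).
#'
#' @param rf an [estimate_rf] result, or a `[channel x H x W]` array.
#' @return Integer channel index.
#' @export
dominant_channel <- function(rf) {
  sp <- if (inherits(rf, "rf_estimate")) rf$spatial_component else rf
  if (length(dim(sp)) != 3L || dim(sp)[1] < 2)
    stop("need a [channel x H x W] spatial component with >= 2 channels")
  peaks <- apply(abs(sp), 1, max)
  idx <- which.max(peaks)
  if (sum(peaks == peaks[idx]) > 1)
    message("dominant_channel: exact tie, returning the lower index")
  as.integer(idx)
}

#' Predictive performance (Pearson correlation)
#'
#' Linear correlation between a predicted trace and the (repeat-averaged)
#' observed response; affine-invariant in either argument.
#'
#' @param pred,truth numeric vectors of equal length >= 2 with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
predictive_cc <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2)
    stop("`pred` and `truth` must have equal length >= 2")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(pred, truth)
}

#' Direction-selectivity permutation test
#'
#' Estimates directional tuning from moving-bar trials: the trial-mean
#' `[time x direction]` response matrix is factorized by SVD into a temporal
#' and a directional component; the directional component (sign-fixed to
#' nonnegative sum, clipped at 0) weights unit vectors at the 8 motion
#' directions, and the length of their vector sum, normalized by the total
#' tuning mass, is the direction selectivity index (in `[0, 1]`; 0 for
#' uniform tuning, 1 for response mass concentrated at one direction). The
#' null distribution is built by shuffling trial
#' direction labels; the p-value is the add-one-corrected fraction of null
#' indices at least as large as the observed one.
#'
#' @param trials a [direction_trials] object or a `[time x direction x
#'   trial]` array.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return An object of class `ds_result` with `ds_index`, `p_value`,
#'   `temporal_component`, `directional_component` and `null` (the permuted
#'   indices).
#' @export
ds_test <- function(trials, n_perm = 1000, seed = 1) {
  resp <- if (inherits(trials, "direction_trials")) trials$responses else trials
  dirs <- if (inherits(trials, "direction_trials")) trials$directions
          else seq(0, by = 360 / dim(resp)[2], length.out = dim(resp)[2])
  d <- dim(resp)
  if (length(d) != 3L || d[2] < 2)
    stop("`trials` must be [time x direction x trial] with >= 2 directions")
  if (d[3] < 2) stop("at least 2 trials per direction required")
  theta <- dirs * pi / 180
  dsi_of <- function(arr) {
    M <- apply(arr, c(1, 2), mean)
    sv <- svd(M)
    v <- sv$v[, 1]
    if (sum(v) < 0) v <- -v
    tuning <- pmax(v, 0)
    mass <- sum(tuning)
    dsi <- if (mass > 0) Mod(sum(tuning * exp(1i * theta))) / mass else 0
    list(dsi = dsi, v = v, u = sv$u[, 1])
  }
  obs <- dsi_of(resp)
  null <- local_seed(seed, {
    flat <- matrix(resp, d[1], d[2] * d[3])
    vapply(seq_len(n_perm), function(i) {
      perm <- flat[, sample.int(ncol(flat))]
      dim(perm) <- d
      dsi_of(perm)$dsi
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs$dsi)) / (n_perm + 1)
  tc <- obs$u
  if (tc[which.max(abs(tc))] < 0) tc <- -tc
  structure(list(ds_index = obs$dsi, p_value = p,
                 temporal_component = tc,
                 directional_component = pmax(obs$v, 0),
                 null = null),
            class = "ds_result")
}

#' Two-sided permutation test for paired model scores
#'
#' Tests whether the mean difference of paired per-neuron scores (e.g., test
#' correlations of two models over the same neurons) differs from zero, using
#' a sign-flip permutation null with add-one correction.
#'
#' @param scores_a,scores_b numeric vectors of equal length >= 2.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
compare_models <- function(scores_a, scores_b, n_perm = 10000, seed = 1) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop("score vectors must have equal length >= 2")
  d <- scores_a - scores_b
  obs <- abs(mean(d))
  null <- local_seed(seed, {
    n <- length(d)
    vapply(seq_len(n_perm), function(i) {
      abs(mean(d * sample(c(-1, 1), n, replace = TRUE)))
    }, numeric(1))
  })
  (1 + sum(null >= obs)) / (n_perm + 1)
}

#' Percentile bootstrap confidence interval for the mean
#'
#' @param values numeric vector with >= 2 elements.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return Named numeric vector `c(lo, hi)`: the 2.5 and 97.5 percentiles of
#'   the bootstrap distribution of the mean.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, seed = 1) {
  if (length(values) < 2) stop("need at least 2 values")
  means <- local_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot), function(i) mean(sample(values, n, replace = TRUE)),
           numeric(1))
  })
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Gaussian-plausibility summary of the shared spatial filters
#'
#' Computes the Gaussian-fit R-squared of every shared convolutional filter
#' on its dominant chromatic channel and returns the per-filter values and
#' their mean. For joint spatio-temporal filters each filter is first
#' factorized into spatial and temporal components by SVD.
#'
#' @param model a [train_model] result.
#' @return List with `r2` (per filter) and `mean_r2`.
#' @export
shared_filter_r2 <- function(model) {
  shared <- model$shared
  cfg <- model$config
  K <- cfg$si$kernel_size
  if (!is.null(shared$W_s) || !is.null(shared$basis_weights)) {
    Ws <- if (!is.null(shared$basis_weights)) {
      geomC <- attr(if (!is.null(model$si)) model$si else model$ec,
                    "geometry")$C
      si_spatial_filters(model$si, cfg$si, geomC)
    } else shared$W_s
    spat <- lapply(seq_len(dim(Ws)[1]), function(i) Ws[i, , , ])
  } else {
    Wc <- shared$W_c
    spat <- lapply(seq_len(dim(Wc)[1]), function(i) {
      factorize_rf(Wc[i, , , , ])$spatial_component
    })
  }
  r2 <- vapply(spat, function(s) {
    if (length(dim(s)) == 3L && dim(s)[1] >= 2) {
      ch <- dominant_channel(s)
      gaussian_fit_r2(s[ch, , ], max_sigma = K)$r_squared
    } else {
      m <- if (length(dim(s)) == 3L) s[1, , ] else s
      gaussian_fit_r2(m, max_sigma = K)$r_squared
    }
  }, numeric(1))
  list(r2 = r2, mean_r2 = mean(r2))
}
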