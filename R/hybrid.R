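#' Hybrid model configuration
#'
#' Settings for joint training of the system-identification (SI) branch and
#' the efficient-coding (EC) autoencoder branch on shared convolutional
#' filters. The total loss is `w * L_SI + (1 - w) * L_EC` with each branch
#' loss normalized by its sample count; branch-private penalties are divided
#' by `w` (resp. `1 - w`) inside the branch loss so their effective strength
#' does not change as `w` varies, while the shared-filter L2 penalties scale
#' with the branch weights. At `w = 0` and `w = 1` the values `1e-8` and
#' `1 - 1e-8` are substituted to avoid division by zero.
#'
#' @param w branch weight in `[0, 1]`; 1 = pure SI, 0 = pure EC.
#' @param si an [si_config] for the SI branch.
#' @param ec an [ec_config] for the EC branch.
#' @param learning_rate Adam learning rate (default 1e-4; doubled
#'   automatically when `data_fraction < 1`).
#' @param max_epochs maximum training epochs (default 100).
#' @param patience consecutive non-improving validation epochs before early
#'   stopping (default 3).
#' @param batch_si,batch_ec mini-batch sizes for the two branches.
#' @param data_fraction leading fraction of the training segment to use
#'   (data-efficiency protocol), in `(0, 1]`.
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(w = 0.2, si = si_config(), ec = ec_config(),
                          learning_rate = 1e-4, max_epochs = 100,
                          patience = 3, batch_si = 32, batch_ec = 32,
                          data_fraction = 1) {
  check_scalar(w, "w", lower = 0, upper = 1)
  check_scalar(data_fraction, "data_fraction", lower = 1e-12, upper = 1)
  stopifnot(inherits(si, "si_config"), inherits(ec, "ec_config"))
  if (!is.null(si$basis) && w < 1)
    stop("basis-constrained spatial filters are a stand-alone SI variant (w = 1)")
  structure(list(w = w, si = si, ec = ec, learning_rate = learning_rate,
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 patience = check_count(patience, "patience"),
                 batch_si = check_count(batch_si, "batch_si"),
                 batch_ec = check_count(batch_ec, "batch_ec"),
                 data_fraction = data_fraction),
            class = "hybrid_config")
}

# Clamp the branch weight away from {0, 1}.
effective_w <- function(w) min(max(w, 1e-8), 1 - 1e-8)

#' Weighted hybrid loss
#'
#' Combines precomputed branch terms into the total training objective
#' \deqn{L = w L_{SI} + (1 - w) L_{EC}}
#' with
#' \deqn{L_{SI} = (Poisson + \alpha_1 \|w_{cs}\|^2 + \alpha_2 \|w_{ct}\|^2/w
#'   + \beta_1 \|w_f\|_1/w) / N_1}
#' \deqn{L_{EC} = (MSE + \alpha_3 \|w_{cs}\|^2 + \alpha_3 \|w_d\|^2/(1-w)
#'   + \beta_2 \|h\|_1/(1-w)) / N_2.}
#' For joint spatio-temporal (3D) filters the temporal-filter term is absent
#' and the shared penalty applies to the joint tensor. At `w` exactly 0 or 1
#' the substitutions `1e-8` / `1 - 1e-8` are used.
#'
#' @param si_terms list with `poisson`, `l2_shared`, `l2_temporal` (0 for 3D),
#'   `l1_readout`, `n` (number of neurons, N1).
#' @param ec_terms list with `mse`, `l2_shared`, `l2_deconv`, `l1_latent`,
#'   `n` (number of images/clips, N2).
#' @param config a [hybrid_config] (its `w` and the penalty weights in
#'   `config$si` / `config$ec` are used).
#' @return A finite scalar.
#' @export
hybrid_loss <- function(si_terms, ec_terms, config) {
  w <- config$w
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]")
  we <- effective_w(w)
  l_si <- (si_terms$poisson +
             config$si$alpha1 * si_terms$l2_shared +
             config$si$alpha2 * si_terms$l2_temporal / we +
             config$si$beta * si_terms$l1_readout / we) / si_terms$n
  l_ec <- (ec_terms$mse +
             config$ec$alpha * ec_terms$l2_shared +
             config$ec$alpha * ec_terms$l2_deconv / (1 - we) +
             config$ec$beta * ec_terms$l1_latent / (1 - we)) / ec_terms$n
  out <- we * l_si + (1 - we) * l_ec
  if (!is.finite(out)) stop("hybrid loss is not finite")
  out
}

# ---- Adam optimizer over a named parameter registry --------------------------

adam_new <- function() new.env(parent = emptyenv())

# Updates env[[name]] in place (the moment buffers and the parameter array
# are private to the training loop; snapshots below take deep copies).
adam_step <- function(state, env, name, grad, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  key_m <- paste0(name, ".m"); key_v <- paste0(name, ".v")
  if (is.null(state[[key_m]])) {
    state[[key_m]] <- grad * 0
    state[[key_v]] <- grad * 0
  }
  adam_update_cpp(env[[name]], state[[key_m]], state[[key_v]], grad,
                  lr, beta1, beta2, eps, 1 - beta1^t, 1 - beta2^t)
  invisible(NULL)
}

deep_copy <- function(lst) {
  lapply(lst, function(v) if (is.numeric(v)) v + 0 else v)
}

snapshot_params <- function(si, ec, shared) {
  list(si = if (!is.null(si)) deep_copy(as.list(si, all.names = TRUE)),
       ec = if (!is.null(ec)) deep_copy(as.list(ec, all.names = TRUE)),
       shared = deep_copy(as.list(shared, all.names = TRUE)))
}

restore_params <- function(si, ec, shared, snap) {
  for (n in names(snap$shared)) shared[[n]] <- snap$shared[[n]]
  if (!is.null(si)) for (n in setdiff(names(snap$si), "shared"))
    si[[n]] <- snap$si[[n]]
  if (!is.null(ec)) for (n in setdiff(names(snap$ec), "shared"))
    ec[[n]] <- snap$ec[[n]]
  invisible(NULL)
}

# Mean Pearson correlation between predicted and observed traces, per neuron.
mean_cc <- function(pred, obs) {
  ccs <- vapply(seq_len(nrow(pred)), function(i) {
    if (stats::sd(pred[i, ]) == 0 || stats::sd(obs[i, ]) == 0) return(NA_real_)
    stats::cor(pred[i, ], obs[i, ])
  }, numeric(1))
  mean(ccs, na.rm = TRUE)
}

# Batched rate prediction at the given stimulus time indices.
si_predict <- function(pars, config, cache, t_idx, chunk = 128) {
  geom <- attr(pars, "geometry")
  out <- matrix(0, geom$n_neurons, length(t_idx))
  for (s in split(seq_along(t_idx), ceiling(seq_along(t_idx) / chunk)))
    out[, s] <- si_step(pars, config, cache, t_idx[s])$pred
  out
}

#' Train a model (stand-alone SI, stand-alone EC, or hybrid)
#'
#' Jointly optimizes the SI and EC branches with Adam on the weighted total
#' loss, taking one gradient step per mini-batch pair. At `w = 1` only the SI
#' branch is instantiated and trained; at `w = 0` only the EC branch.
#' Training stops after `max_epochs` or when the validation metric (mean
#' single-trial correlation for models with an SI branch, negative
#' reconstruction error for pure EC) has not improved for `patience`
#' consecutive epochs; the best-validation snapshot is returned.
#'
#' @param data list with `stimulus` (a [stimulus_movie]) and `responses`
#'   (a [response_set]).
#' @param ec_corpus an [image_corpus] (2D EC mode) or a [stimulus_movie]
#'   (3D EC modes); may be `NULL` for pure SI training.
#' @param config a [hybrid_config].
#' @param seed integer seed controlling initialization, batching and encoder
#'   noise; identical seeds give identical training runs.
#' @return An object of class `trained_model` with elements `si`, `ec`,
#'   `shared` (parameter environments; `si` and `ec` reference the same
#'   `shared`), `config`, `history` (per-epoch train loss and validation
#'   metric), `stopped_epoch`, `best_epoch`, `best_val`, `seed`.
#' @export
train_model <- function(data, ec_corpus = NULL, config = hybrid_config(),
                        seed = 1) {
  stopifnot(inherits(config, "hybrid_config"),
            inherits(data$stimulus, "stimulus_movie"),
            inherits(data$responses, "response_set"))
  w <- config$w
  use_si <- w > 0
  use_ec <- w < 1
  if (use_ec && is.null(ec_corpus))
    stop("`ec_corpus` is required whenever the EC branch is active (w < 1)")
  resp <- data$responses
  cache <- stim_cache(data$stimulus)
  L <- config$si$n_lags
  n_neurons <- nrow(resp$train_traces)

  # leading-fraction truncation of the training segment (data efficiency)
  tr_idx <- resp$stim_split$train
  n_used <- max(1L, floor(length(tr_idx) * config$data_fraction))
  tr_idx <- tr_idx[seq_len(n_used)]
  tr_targets <- resp$train_traces[, seq_len(n_used), drop = FALSE]
  keep <- tr_idx >= L
  tr_idx <- tr_idx[keep]
  tr_targets <- tr_targets[, keep, drop = FALSE]
  if (length(tr_idx) < config$batch_si)
    stop("training segment shorter than one mini-batch")
  lr <- config$learning_rate * if (config$data_fraction < 1) 2 else 1

  # EC corpus in internal layout
  ec3d <- config$ec$mode != "image2d"
  if (use_ec) {
    if (ec3d) {
      stopifnot(inherits(ec_corpus, "stimulus_movie"))
      ec_frames <- aperm(ec_corpus$frames, c(3, 4, 2, 1))   # (H,W,C,T)
      ec_n <- dim(ec_corpus$frames)[1] - config$ec$n_lags + 1
      if (ec_n < 1) stop("EC movie shorter than one clip")
    } else {
      stopifnot(inherits(ec_corpus, "image_corpus"))
      ec_imgs <- aperm(ec_corpus$images, c(3, 4, 2, 1))     # (H,W,C,n)
      ec_n <- dim(ec_corpus$images)[1]
    }
  }

  local_seed(seed, {
    si <- NULL; ec <- NULL; shared <- NULL
    if (use_si) {
      si <- si_init(config$si, n_neurons, cache$H, cache$W, cache$C,
                    seed = seed)
      shared <- si$shared
      # initialize the readout bias at the log mean rate
      si$b_f <- rep(log(mean(tr_targets) + 1e-6), n_neurons)
    }
    if (use_ec) {
      gec <- if (ec3d) dim(ec_frames) else dim(ec_imgs)
      ec <- ec_init(config$ec, gec[1], gec[2], gec[3], seed = seed + 1,
                    shared = shared)
      if (is.null(shared)) shared <- ec$shared
    }
    we <- effective_w(w)
    shared_name <- if (!is.null(config$si$basis)) "basis_weights"
                   else if ((use_si && config$si$mode == "spatiotemporal3d") ||
                            (!use_si && ec3d)) "W_c" else "W_s"

    state <- adam_new()
    t_adam <- 0L
    ec_perm <- integer(0); ec_ptr <- 1L
    next_ec_batch <- function() {
      bs <- min(config$batch_ec, ec_n)
      if (ec3d) {
        # contiguous clip runs keep the per-batch frame set small
        start <- sample.int(ec_n - bs + 1L, 1L)
        return(start:(start + bs - 1L))
      }
      if (ec_ptr + bs - 1L > length(ec_perm)) {
        ec_perm <<- sample.int(ec_n)
        ec_ptr <<- 1L
      }
      idx <- ec_perm[ec_ptr:(ec_ptr + bs - 1L)]
      ec_ptr <<- ec_ptr + bs
      idx
    }
    build_ec_batch <- function(idx) {
      if (!ec3d) {
        x <- ec_imgs[, , , idx, drop = FALSE]
        list(x = x, target = x)
      } else {
        Lc <- config$ec$n_lags
        tt <- idx + Lc - 1L                     # window end frames
        umat <- matrix(rep(tt, each = Lc) + ((1:Lc) - Lc), Lc, length(tt))
        x <- ec_frames[, , , as.vector(umat), drop = FALSE]
        dim(x) <- c(dim(ec_frames)[1:3], Lc, length(tt))
        if (config$ec$mode == "future3d") {
          tgt <- ec_frames[, , , tt, drop = FALSE]
          x[, , , Lc, ] <- apply(x[, , , seq_len(Lc - 1), , drop = FALSE],
                                 c(1, 2, 3, 5), mean)
        } else {
          tgt <- ec_frames[, , , tt - 1L, drop = FALSE]
        }
        list(x = x, target = tgt)
      }
    }

    n_steps <- if (use_si) max(1L, floor(length(tr_idx) / config$batch_si))
               else max(1L, ceiling(ec_n / config$batch_ec))
    # per-batch data sums are scaled up to dataset level before the division
    # by N1 (neurons) and N2 (corpus images), so each step optimizes an
    # unbiased estimate of the dataset-level objective and the fixed weight
    # penalties keep their intended relative strength
    t_eff <- length(tr_idx)
    # contiguous mini-batch blocks: clips inside a block overlap heavily, so
    # each step touches ~(batch + n_lags) stimulus frames instead of ~8x that
    si_blocks <- if (use_si)
      split(seq_len(n_steps * config$batch_si),
            rep(seq_len(n_steps), each = config$batch_si))
    best_val <- -Inf; best_snap <- NULL; best_epoch <- 0L
    bad_epochs <- 0L; history <- vector("list", config$max_epochs)
    stopped_epoch <- config$max_epochs

    for (epoch in seq_len(config$max_epochs)) {
      blk_order <- if (use_si) sample.int(n_steps) else integer(0)
      epoch_loss <- 0
      for (step in seq_len(n_steps)) {
        t_adam <- t_adam + 1L
        grads <- list()
        si_terms <- list(poisson = 0, l2_shared = 0, l2_temporal = 0,
                         l1_readout = 0, n = max(1, n_neurons))
        ec_terms <- list(mse = 0, l2_shared = 0, l2_deconv = 0,
                         l1_latent = 0, n = 1)
        if (use_si) {
          bi <- si_blocks[[blk_order[step]]]
          tgt <- tr_targets[, bi, drop = FALSE]
          up_si <- t_eff / length(bi)          # batch -> dataset scale
          fwd <- si_step(si, config$si, cache, tr_idx[bi], targets = tgt,
                         dscale = we * up_si / n_neurons)
          grads <- fwd$grads
          terms <- fwd$pred
          pos <- tgt > 0
          terms[pos] <- fwd$pred[pos] - tgt[pos] * fwd$Z[pos]
          si_terms$poisson <- sum(terms) * up_si
          Ws <- if (is.null(config$si$basis)) shared[[shared_name]]
                else si_spatial_filters(si, config$si, cache$C)
          si_terms$l2_shared <- l2sq(Ws)
          if (config$si$mode == "factorized2d") {
            si_terms$l2_temporal <- l2sq(si$W_t)
            grads$W_t <- grads$W_t + (2 * config$si$alpha2 / n_neurons) * si$W_t
          }
          si_terms$l1_readout <- l1(si$W_f)
          grads$W_f <- grads$W_f + (config$si$beta / n_neurons) * sign(si$W_f)
          gpen <- (2 * we * config$si$alpha1 / n_neurons) * Ws
          if (!is.null(config$si$basis)) {
            grads$basis_weights <- grads$basis_weights +
              basis_weight_grad(gpen, config$si$basis, cache$C)
          } else {
            grads[[shared_name]] <- grads[[shared_name]] + gpen
          }
        }
        if (use_ec) {
          eb <- build_ec_batch(next_ec_batch())
          nb <- if (ec3d) dim(eb$x)[5] else dim(eb$x)[4]
          up_ec <- ec_n / nb                   # batch -> dataset scale
          ec_terms$n <- ec_n
          ecr <- ec_step(ec, config$ec, eb$x, target = eb$target,
                         noise = TRUE, backward = TRUE,
                         scales = list(mse = (1 - we) * up_ec / ec_n,
                                       l1 = config$ec$beta * up_ec / ec_n))
          eg <- ecr$grads
          ec_terms$mse <- ecr$mse * up_ec
          ec_terms$l1_latent <- ecr$l1h * up_ec
          ec_terms$l2_shared <- l2sq(shared[[shared_name]])
          ec_terms$l2_deconv <- l2sq(ec$W_dec)
          eg$W_dec <- eg$W_dec + (2 * config$ec$alpha / ec_n) * ec$W_dec
          eg[[shared_name]] <- eg[[shared_name]] +
            (2 * (1 - we) * config$ec$alpha / ec_n) * shared[[shared_name]]
          for (nm in names(eg)) {
            grads[[nm]] <- if (is.null(grads[[nm]])) eg[[nm]]
                           else grads[[nm]] + eg[[nm]]
          }
        }
        batch_loss <- hybrid_loss(si_terms, ec_terms, config)
        if (!is.finite(batch_loss))
          stop(sprintf("training diverged at epoch %d step %d", epoch, step))
        epoch_loss <- epoch_loss + batch_loss
        for (nm in names(grads)) {
          env <- if (nm %in% c("W_s", "W_c", "basis_weights")) shared
                 else if (nm %in% c("W_t", "W_f", "b_f")) si else ec
          adam_step(state, env, nm, grads[[nm]], lr, t_adam)
        }
      }
      # validation metric
      if (use_si) {
        vp <- si_predict(si, config$si, cache, resp$stim_split$val)
        val <- mean_cc(vp, resp$val_traces)
      } else {
        idx <- seq_len(min(ec_n, 200L))
        eb <- build_ec_batch(idx)
        ev <- ec_step(ec, config$ec, eb$x, target = eb$target, noise = FALSE)
        val <- -ev$mse / length(idx)
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = epoch_loss / n_steps,
                                     val_metric = val)
      if (is.finite(val) && val > best_val) {
        best_val <- val; best_epoch <- epoch
        best_snap <- snapshot_params(si, ec, shared)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }
    if (!is.null(best_snap)) restore_params(si, ec, shared, best_snap)
    structure(list(si = si, ec = ec, shared = shared, config = config,
                   history = do.call(rbind, history[!vapply(history, is.null,
                                                            logical(1))]),
                   stopped_epoch = stopped_epoch, best_epoch = best_epoch,
                   best_val = best_val, seed = seed),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> w = %g, stopped at epoch %d (best %d, val %.4f)\n",
              x$config$w, x$stopped_epoch, x$best_epoch, x$best_val))
  invisible(x)
}

#' Predict rates from a trained model
#'
#' @param object a [train_model] result with an SI branch.
#' @param stimulus the [stimulus_movie] to predict on.
#' @param t_idx stimulus frame indices to predict (default: every frame from
#'   `n_lags` on).
#' @param ... unused.
#' @return Matrix `[n_neurons x length(t_idx)]` of predicted rates.
#' @export
predict.trained_model <- function(object, stimulus, t_idx = NULL, ...) {
  if (is.null(object$si)) stop("model has no SI branch (w = 0)")
  cache <- stim_cache(stimulus)
  if (is.null(t_idx)) t_idx <- seq(object$config$si$n_lags, cache$T)
  si_predict(object$si, object$config$si, cache, t_idx)
}

#' Evaluate a trained model on the held-out test sequence
#'
#' Predicts the repeated test sequence and correlates the prediction with
#' the repeat-averaged observed response, per neuron.
#'
#' @param model a [train_model] result with an SI branch.
#' @param data the list of `stimulus` and `responses` used for training.
#' @return List with `cc` (per-neuron Pearson correlation on the test
#'   sequence) and `mean_cc`.
#' @export
evaluate_model <- function(model, data) {
  resp <- data$responses
  test_idx <- resp$stim_split$test
  pred <- predict(model, data$stimulus, test_idx)
  truth <- apply(resp$test_block, c(1, 3), mean)   # repeat average
  cc <- vapply(seq_len(nrow(pred)), function(i) {
    if (stats::sd(pred[i, ]) == 0 || stats::sd(truth[i, ]) == 0)
      return(NA_real_)
    stats::cor(pred[i, ], truth[i, ])
  }, numeric(1))
  list(cc = cc, mean_cc = mean(cc, na.rm = TRUE))
}

#' Hyperparameter sweep
#'
#' Trains one model per (value, seed) combination for a swept parameter and
#' reports the mean validation metric per value, selecting the argmax.
#' Supported parameters: `"w"` (branch weight) and `"n_bases"` (number of
#' DCT or PCA basis elements for a basis-constrained stand-alone SI model).
#'
#' @param parameter `"w"` or `"n_bases"`.
#' @param values vector of values to sweep.
#' @param base_config a [hybrid_config] used as template.
#' @param data training data (see [train_model]).
#' @param ec_corpus corpus for the EC branch (ignored for `n_bases`).
#' @param seeds integer vector of seeds (>= 1 required).
#' @param basis_kind `"dct"` or `"pca"` for the `n_bases` sweep.
#' @param basis_corpus [image_corpus] used to build PCA bases.
#' @return List with `table` (data.frame of value, mean/sd of the validation
#'   metric) and `selected` (argmax value).
#' @export
sweep_hyperparameter <- function(parameter = c("w", "n_bases"), values,
                                 base_config, data, ec_corpus = NULL,
                                 seeds = 1:3, basis_kind = c("dct", "pca"),
                                 basis_corpus = NULL) {
  parameter <- match.arg(parameter)
  basis_kind <- match.arg(basis_kind)
  if (length(values) < 1) stop("`values` must be nonempty")
  if (length(seeds) < 1) stop("at least one seed is required")
  rows <- list()
  for (v in values) {
    vals <- numeric(0)
    for (s in seeds) {
      cfg <- base_config
      if (parameter == "w") {
        cfg$w <- v
      } else {
        K <- cfg$si$kernel_size
        basis <- if (basis_kind == "dct") make_dct_basis(K, v)
                 else make_pca_basis(basis_corpus, v, patch_size = K)
        cfg$si$basis <- basis
        cfg$w <- 1
      }
      m <- train_model(data, ec_corpus, cfg, seed = s)
      vals <- c(vals, m$best_val)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(value = v, mean_val = mean(vals), sd_val = stats::sd(vals))
  }
  tab <- do.call(rbind, rows)
  list(table = tab, selected = tab$value[which.max(tab$mean_val)])
}
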