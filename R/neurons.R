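#' Ground-truth model neuron
#'
#' A linear-nonlinear (LN) neuron with a difference-of-Gaussians (DoG)
#' spatial receptive field, a biphasic temporal kernel (unit L2 norm), a
#' pointwise output nonlinearity and additive trial noise. Used as simulation
#' ground truth for recovery experiments.
#'
#' @param spatial_rf numeric array `[channel x height x width]`.
#' @param temporal_kernel numeric vector over lags (oldest first); stored
#'   normalized to unit L2 norm.
#' @param output_nonlinearity `"softplus"` or `"exponential"`.
#' @param gain,threshold parameters of the output nonlinearity
#'   `g(gain * (drive - threshold))`.
#' @param trial_noise_sd standard deviation of the additive Gaussian trial
#'   noise on the firing rate (rates are clipped at zero).
#' @param direction_tuning `NULL`, or `list(preferred_angle, strength)` with
#'   angle in degrees and strength in `[0, 1]`.
#' @return An object of class `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(spatial_rf, temporal_kernel,
                                output_nonlinearity = c("softplus", "exponential"),
                                gain = 2, threshold = 0.5,
                                trial_noise_sd = 1.0,
                                direction_tuning = NULL) {
  output_nonlinearity <- match.arg(output_nonlinearity)
  stopifnot(is.array(spatial_rf), length(dim(spatial_rf)) == 3L)
  nk <- sqrt(sum(temporal_kernel^2))
  if (nk == 0) stop("`temporal_kernel` must be nonzero")
  check_scalar(trial_noise_sd, "trial_noise_sd", lower = 0)
  structure(list(spatial_rf = spatial_rf,
                 temporal_kernel = temporal_kernel / nk,
                 output_nonlinearity = output_nonlinearity,
                 gain = gain, threshold = threshold,
                 trial_noise_sd = trial_noise_sd,
                 direction_tuning = direction_tuning),
            class = "ground_truth_neuron")
}

# Difference-of-Gaussians spatial map on an h x w pixel grid.
dog_map <- function(h, w, cy, cx, sigma_c, sigma_s, surround_weight) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  center <- exp(-d2 / (2 * sigma_c^2))
  surround <- exp(-d2 / (2 * sigma_s^2))
  center - surround_weight * (sigma_c^2 / sigma_s^2) * surround
}

# Biphasic temporal kernel over `n_lags` frames, oldest lag first; the most
# recent frames carry the main (positive) lobe, earlier frames the opposite
# rebound lobe. Unit L2 norm.
biphasic_kernel <- function(n_lags, peak_lag = 1.0, rebound_lag = 3.0,
                            rebound_weight = 0.7) {
  tau <- (n_lags - 1):0          # time before response, in frames
  k <- exp(-((tau - peak_lag) / 0.8)^2) -
    rebound_weight * exp(-((tau - rebound_lag) / 1.5)^2)
  k / sqrt(sum(k^2))
}

#' Response-set container
#'
#' Per-neuron event-rate traces split into training and validation segments
#' plus a repeated test block, with the stimulus frame indices of each
#' segment. The repeat-averaged test block is the ground truth for the
#' predictive-performance metric.
#'
#' @param train_traces,val_traces numeric matrices `[neuron x time]`.
#' @param test_block numeric array `[neuron x repeat x test_time]`.
#' @param sampling_rate sampling rate in Hz.
#' @param stim_split list of integer frame-index vectors `train`, `val`,
#'   `test` into the companion stimulus movie.
#' @param qi_noise optional per-neuron response quality index; computed from
#'   `test_block` via [quality_index] when missing.
#' @return An object of class `response_set`.
#' @export
response_set <- function(train_traces, val_traces, test_block, sampling_rate,
                         stim_split, qi_noise = NULL) {
  stopifnot(is.matrix(train_traces), is.matrix(val_traces),
            is.array(test_block), length(dim(test_block)) == 3L)
  if (dim(test_block)[2] < 2)
    stop("`test_block` needs at least 2 repeats for the quality index")
  if (anyNA(train_traces) || anyNA(val_traces) || anyNA(test_block))
    stop("response traces must be free of NA")
  n <- nrow(train_traces)
  if (is.null(qi_noise)) {
    qi_noise <- vapply(seq_len(n), function(i) {
      C <- t(test_block[i, , ])   # [time x repeat]
      if (all(apply(C, 2, stats::var) == 0)) return(NA_real_)
      quality_index(C)
    }, numeric(1))
  }
  structure(list(train_traces = train_traces, val_traces = val_traces,
                 test_block = test_block, sampling_rate = sampling_rate,
                 stim_split = stim_split, qi_noise = qi_noise),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf(paste0("<response_set> %d neurons; train %d, val %d frames; ",
                     "test %d repeats x %d frames; median QI %.3f\n"),
              nrow(x$train_traces), ncol(x$train_traces), ncol(x$val_traces),
              dim(x$test_block)[2], dim(x$test_block)[3],
              stats::median(x$qi_noise, na.rm = TRUE)))
  invisible(x)
}

#' Simulate an LN population responding to a stimulus movie
#'
#' Each neuron's firing rate is a pointwise nonlinearity applied to the
#' projection of the temporally filtered stimulus onto its DoG spatial
#' receptive field. Observed traces are the rate plus independent Gaussian
#' trial noise, clipped at zero (emulating nonnegative event rates derived
#' from Ca2+ transients). The final `test_frames` of the movie form the test
#' sequence, simulated `n_test_repeats` times with fresh noise; the remaining
#' frames are split ~91%/9% into train/validation.
#'
#' @param n_neurons number of neurons.
#' @param stimulus a [stimulus_movie].
#' @param rf_params list of template ranges overriding the defaults:
#'   `sigma_center` (range, px), `surround_scale`, `surround_weight`,
#'   `n_lags`, `gain`, `threshold`, `trial_noise_sd`, `off_fraction`,
#'   `population` (`"ventral"` = UV-dominant, `"dorsal"` = green-dominant,
#'   `"mixed"`), `secondary_weight` (range for the non-dominant channel),
#'   `output_nonlinearity`.
#' @param n_test_repeats number of simulated test-sequence repeats.
#' @param test_frames length of the test sequence in frames (default: 10 s
#'   worth of frames).
#' @param seed integer seed.
#' @return A list with elements `responses` (a [response_set]) and `neurons`
#'   (list of [ground_truth_neuron]).
#' @export
simulate_ln_population <- function(n_neurons, stimulus, rf_params = list(),
                                   n_test_repeats = 6, test_frames = NULL,
                                   seed = 1) {
  stopifnot(inherits(stimulus, "stimulus_movie"))
  n_neurons <- check_count(n_neurons, "n_neurons")
  n_test_repeats <- check_count(n_test_repeats, "n_test_repeats")
  p <- modifyList(list(sigma_center = c(1.2, 2.0), surround_scale = 2.0,
                       surround_weight = 0.6, n_lags = 8L, gain = 2,
                       threshold = 0.5, trial_noise_sd = 1.0,
                       off_fraction = 0.5, population = "ventral",
                       secondary_weight = c(0.05, 0.3),
                       output_nonlinearity = "softplus"),
                  rf_params)
  d <- dim(stimulus$frames)
  T_all <- d[1]; nc <- d[2]; h <- d[3]; w <- d[4]
  L <- as.integer(p$n_lags)
  if (is.null(test_frames)) test_frames <- round(10 * stimulus$frame_rate)
  test_frames <- check_count(test_frames, "test_frames")
  if (T_all < test_frames + 2 * L + 20)
    stop("stimulus too short for train + validation + test segments")
  n_rest <- T_all - test_frames
  n_train <- round(n_rest * 440 / 480)
  n_val <- n_rest - n_train
  if (n_val < 1) stop("stimulus too short for a validation segment")
  split <- list(train = seq_len(n_train),
                val = n_train + seq_len(n_val),
                test = n_rest + seq_len(test_frames))

  stim_mat <- matrix(stimulus$frames, nrow = T_all)  # [T x (C*H*W)]

  out <- local_seed(seed, {
    neurons <- vector("list", n_neurons)
    rates <- matrix(0, n_neurons, T_all)
    for (i in seq_len(n_neurons)) {
      sc <- runif(1, p$sigma_center[1], max(p$sigma_center))
      ss <- sc * p$surround_scale
      margin <- ceiling(2 * sc) + 1
      cy <- runif(1, margin, h - margin + 1)
      cx <- runif(1, margin, w - margin + 1)
      polarity <- if (runif(1) < p$off_fraction) -1 else 1
      dom <- switch(p$population,
                    ventral = 1L, dorsal = min(2L, nc),
                    sample.int(nc, 1))
      wts <- runif(nc, p$secondary_weight[1], max(p$secondary_weight))
      wts[dom] <- 1
      rf <- array(0, dim = c(nc, h, w))
      spot <- polarity * dog_map(h, w, cy, cx, sc, ss, p$surround_weight)
      for (c in seq_len(nc)) rf[c, , ] <- wts[c] * spot
      rf <- rf / sqrt(sum(rf^2))
      kern <- biphasic_kernel(L, peak_lag = runif(1, 0.8, 1.4),
                              rebound_lag = runif(1, 2.5, 3.5))
      nrn <- ground_truth_neuron(rf, kern,
                                 output_nonlinearity = p$output_nonlinearity,
                                 gain = p$gain, threshold = p$threshold,
                                 trial_noise_sd = p$trial_noise_sd)
      proj <- as.vector(stim_mat %*% as.vector(rf))
      filt <- rev(nrn$temporal_kernel)  # filter() weights: most recent first
      drive <- as.vector(stats::filter(proj, filt, method = "convolution",
                                       sides = 1))
      drive[seq_len(L - 1)] <- 0
      z <- nrn$gain * (drive - nrn$threshold)
      rates[i, ] <- switch(nrn$output_nonlinearity,
                           softplus = softplus(z), exponential = exp(z))
      neurons[[i]] <- nrn
    }
    noisy <- function(r) {
      if (p$trial_noise_sd == 0) return(r)
      pmax(r + rnorm(length(r), sd = p$trial_noise_sd), 0)
    }
    train_traces <- matrix(0, n_neurons, n_train)
    val_traces <- matrix(0, n_neurons, n_val)
    test_block <- array(0, dim = c(n_neurons, n_test_repeats, test_frames))
    for (i in seq_len(n_neurons)) {
      train_traces[i, ] <- noisy(rates[i, split$train])
      val_traces[i, ] <- noisy(rates[i, split$val])
      for (r in seq_len(n_test_repeats))
        test_block[i, r, ] <- noisy(rates[i, split$test])
    }
    list(neurons = neurons, train = train_traces, val = val_traces,
         test = test_block)
  })
  resp <- response_set(out$train, out$val, out$test,
                       sampling_rate = stimulus$frame_rate, stim_split = split)
  list(responses = resp, neurons = out$neurons)
}

#' Direction-trials container
#'
#' Responses to a bright bar moving in 8 directions, with at least two trials
#' per direction.
#'
#' @param responses numeric array `[time x direction x trial]`.
#' @param directions direction angles in degrees (8 values).
#' @return An object of class `direction_trials`.
#' @export
direction_trials <- function(responses, directions = seq(0, 315, by = 45)) {
  stopifnot(is.array(responses), length(dim(responses)) == 3L)
  if (length(directions) != 8 || dim(responses)[2] != 8)
    stop("the moving-bar protocol uses 8 directions")
  if (dim(responses)[3] < 2) stop("at least 2 trials per direction required")
  structure(list(responses = responses, directions = directions),
            class = "direction_trials")
}

#' Simulate moving-bar direction trials
#'
#' Each cell responds to 8 motion directions with a shared temporal profile
#' scaled by a von Mises-modulated directional amplitude; strength 0 yields
#' an untuned cell (all directions share one mean amplitude), strength 1 a
#' response concentrated at the preferred direction. Independent Gaussian
#' noise is added per trial.
#'
#' @param n_cells number of cells.
#' @param tuning_strengths vector in `[0, 1]`, recycled over cells.
#' @param n_trials trials per direction (>= 2).
#' @param n_time time samples per trial.
#' @param noise_sd trial noise standard deviation.
#' @param kappa von Mises concentration of the tuning curve.
#' @param seed integer seed.
#' @return A list of [direction_trials]; each element carries attributes
#'   `preferred_angle` and `tuning_strength`.
#' @export
simulate_direction_trials <- function(n_cells, tuning_strengths = 0,
                                      n_trials = 4, n_time = 12,
                                      noise_sd = 0.2, kappa = 5, seed = 1) {
  n_cells <- check_count(n_cells, "n_cells")
  if (n_trials < 2) stop("`n_trials` must be at least 2")
  if (any(tuning_strengths < 0 | tuning_strengths > 1))
    stop("`tuning_strengths` must lie in [0, 1]")
  strengths <- rep_len(tuning_strengths, n_cells)
  dirs <- seq(0, 315, by = 45)
  profile <- exp(-((seq_len(n_time) - n_time / 3)^2) / (2 * (n_time / 6)^2))
  local_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      s <- strengths[i]
      pref <- runif(1, 0, 360)
      vm <- exp(kappa * (cos((dirs - pref) * pi / 180) - 1))
      amp <- (1 - s) + s * vm
      resp <- array(0, dim = c(n_time, 8, n_trials))
      for (d in seq_len(8)) for (tr in seq_len(n_trials))
        resp[, d, tr] <- amp[d] * profile +
          if (noise_sd > 0) rnorm(n_time, sd = noise_sd) else 0
      out <- direction_trials(resp, dirs)
      attr(out, "preferred_angle") <- pref
      attr(out, "tuning_strength") <- s
      out
    })
  })
}
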