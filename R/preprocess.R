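#' Response quality index
#'
#' Reliability of a repeated response: the variance over time of the
#' repeat-averaged response, divided by the repeat-averaged variance over
#' time of the individual repeats,
#' \deqn{QI = Var_t[ E_r[C] ] / E_r[ Var_t[C] ],}
#' for a `[time x repeat]` response matrix `C`. `QI` lies in `[0, 1]` (up to
#' floating error): identical repeats give 1, independent noise gives about
#' `1/r` for `r` repeats. The index is invariant to scaling and offsets of
#' the response.
#'
#' @param C numeric matrix `[time x repeat]` with at least 2 repeats.
#' @return A single number in `[0, 1]`.
#' @export
quality_index <- function(C) {
  if (!is.matrix(C) || ncol(C) < 2)
    stop("`C` must be a [time x repeat] matrix with >= 2 repeats")
  if (anyNA(C)) stop("`C` must be free of NA")
  denom <- mean(apply(C, 2, stats::var))
  if (denom == 0)
    stop("all repeats are constant in time: quality index is undefined (0/0)")
  stats::var(rowMeans(C)) / denom
}

#' Preprocess a raw activity trace
#'
#' Conditioning pipeline for slow fluorescence-derived activity traces, in
#' order: z-normalize (zero mean, unit SD); linearly interpolate from the
#' recording rate `fs_in` to the stimulus rate `fs_out`; detrend with a
#' zero-phase (forward-backward) 2nd-order Butterworth high-pass filter at
#' `highpass_hz`; take the first-order difference; clip negative values to
#' zero. The result is a nonnegative event-rate-like trace aligned to
#' stimulus frames (one sample shorter than the interpolated trace).
#'
#' @param raw numeric vector, the raw trace.
#' @param fs_in sampling rate of `raw` in Hz.
#' @param fs_out target sampling rate in Hz.
#' @param highpass_hz high-pass cutoff in Hz (default 0.1); 0 disables the
#'   detrending stage.
#' @return Numeric vector, nonnegative.
#' @export
preprocess_trace <- function(raw, fs_in, fs_out, highpass_hz = 0.1) {
  check_scalar(fs_in, "fs_in", lower = 1e-9)
  check_scalar(fs_out, "fs_out", lower = 1e-9)
  if (length(raw) < 2) stop("`raw` must have length >= 2")
  if (anyNA(raw)) stop("`raw` must be free of NA")
  s <- stats::sd(raw)
  if (s == 0) stop("constant raw trace: z-normalization would divide by zero")
  z <- (raw - mean(raw)) / s
  t_in <- (seq_along(z) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  zi <- stats::approx(t_in, z, xout = t_out)$y
  wn <- highpass_hz / (fs_out / 2)
  if (highpass_hz > 0 && wn < 1) {
    bf <- signal::butter(2, wn, type = "high")
    zi <- signal::filtfilt(bf, zi)
  }
  d <- diff(zi)
  d[d < 0] <- 0
  d
}

#' Train/validation/test frame assignment
#'
#' Splits the non-test portion of a recording into contiguous training and
#' validation segments. Two named schemes reproduce the standard recording
#' layouts: `"noise"` (480 s of non-test data, 440 s train / 40 s validation)
#' and `"movie"` (540 s, 433 s train / 107 s validation). A custom scheme can
#' be given as `c(train_s, val_s)`. `fraction < 1` truncates the training
#' segment to its leading fraction (the data-efficiency protocol); validation
#' and test are untouched.
#'
#' @param n_frames total number of non-test frames available.
#' @param frame_rate frames per second.
#' @param scheme `"noise"`, `"movie"`, or a numeric `c(train_s, val_s)` in
#'   seconds.
#' @param fraction fraction of the training segment to keep, in `(0, 1]`.
#' @return List with integer index vectors `train` and `val` (disjoint,
#'   jointly covering the scheme's span) and the segment lengths in frames.
#' @export
split_sequences <- function(n_frames, frame_rate, scheme = "noise",
                            fraction = 1) {
  n_frames <- check_count(n_frames, "n_frames")
  check_scalar(frame_rate, "frame_rate", lower = 1e-9)
  check_scalar(fraction, "fraction", lower = 1e-12, upper = 1)
  if (is.character(scheme)) {
    scheme <- match.arg(scheme, c("noise", "movie"))
    secs <- switch(scheme, noise = c(440, 40), movie = c(433, 107))
  } else {
    stopifnot(is.numeric(scheme), length(scheme) == 2L, all(scheme > 0))
    secs <- scheme
  }
  n_train <- round(secs[1] * frame_rate)
  n_val <- round(secs[2] * frame_rate)
  if (n_train + n_val > n_frames)
    stop(sprintf("scheme needs %d frames but only %d are available",
                 n_train + n_val, n_frames))
  n_used <- max(1L, floor(n_train * fraction))
  list(train = seq_len(n_used),
       val = n_train + seq_len(n_val),
       n_train_full = n_train, n_train_used = n_used, n_val = n_val)
}
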