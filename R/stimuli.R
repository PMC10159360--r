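#' Stimulus movie container
#'
#' A chromatic frame sequence used as input to the encoding models and as an
#' image source for the autoencoder branch. Frames are stored as a
#' `[time x channel x height x width]` array with values in `[-1, 1]` so that
#' every model input lives in the range representable by the autoencoder's
#' tanh output.
#'
#' @param frames numeric array `[time x channel x height x width]`, all values
#'   in `[-1, 1]`.
#' @param frame_rate frame rate in Hz.
#' @param channel_names character vector naming the chromatic channels.
#' @return An object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, frame_rate,
                           channel_names = c("UV", "green")[seq_len(dim(frames)[2])]) {
  if (!is.array(frames) || length(dim(frames)) != 4L)
    stop("`frames` must be a 4-d array [time x channel x height x width]")
  if (!all(is.finite(frames))) stop("`frames` must be finite")
  if (max(abs(frames)) > 1 + 1e-12) stop("`frames` values must lie in [-1, 1]")
  check_scalar(frame_rate, "frame_rate", lower = 1e-9)
  if (length(channel_names) != dim(frames)[2])
    stop("`channel_names` length must match the channel dimension")
  structure(list(frames = frames, frame_rate = frame_rate,
                 channel_names = channel_names),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %d frames, %d channel(s) (%s), %dx%d px @ %g Hz\n",
              d[1], d[2], paste(x$channel_names, collapse = "/"), d[3], d[4],
              x$frame_rate))
  invisible(x)
}

#' Image corpus container
#'
#' A set of images used to train the autoencoder branch. `provenance` records
#' how the corpus was generated: `structured` (1/f images with phase
#' structure), `phase_scrambled` (same second-order statistics, randomized
#' phases) or `white_noise`.
#'
#' @param images numeric array `[n x channel x height x width]` in `[-1, 1]`.
#' @param provenance one of `"structured"`, `"phase_scrambled"`,
#'   `"white_noise"`.
#' @return An object of class `image_corpus`.
#' @export
image_corpus <- function(images, provenance = c("structured", "phase_scrambled",
                                                "white_noise")) {
  provenance <- match.arg(provenance)
  if (!is.array(images) || length(dim(images)) != 4L)
    stop("`images` must be a 4-d array [n x channel x height x width]")
  if (!all(is.finite(images))) stop("`images` must be finite")
  if (max(abs(images)) > 1 + 1e-12) stop("`images` values must lie in [-1, 1]")
  structure(list(images = images, provenance = provenance),
            class = "image_corpus")
}

#' @export
print.image_corpus <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_corpus> %d images, %d channel(s), %dx%d px, provenance: %s\n",
              d[1], d[2], d[3], d[4], x$provenance))
  invisible(x)
}

#' Binary dense-noise stimulus
#'
#' Generates chromatic binary dense noise: every pixel of every frame and
#' channel is independently `+1` or `-1` with probability one half. The
#' default geometry (28x28 px, two chromatic channels, 5 Hz) matches the
#' dense-noise stimulus the encoding models are built for.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames.
#' @param n_channels number of chromatic channels.
#' @param frame_rate frame rate in Hz.
#' @param seed integer seed; identical seeds give bit-identical stimuli.
#' @return A [stimulus_movie].
#' @export
generate_binary_noise <- function(height = 28, width = 28, n_frames = 100,
                                  n_channels = 2, frame_rate = 5, seed = 1) {
  height <- check_count(height, "height"); width <- check_count(width, "width")
  n_frames <- check_count(n_frames, "n_frames")
  n_channels <- check_count(n_channels, "n_channels")
  vals <- local_seed(seed, {
    2 * rbinom(n_frames * n_channels * height * width, 1L, 0.5) - 1
  })
  frames <- array(as.double(vals), dim = c(n_frames, n_channels, height, width))
  ch <- if (n_channels == 2) c("UV", "green") else paste0("ch", seq_len(n_channels))
  stimulus_movie(frames, frame_rate, ch)
}

# Target amplitude spectrum on the 2-d FFT grid: |f|^-gamma with zero DC.
spectral_amplitude_grid <- function(height, width, gamma) {
  fy <- c(0:floor(height / 2), -(ceiling(height / 2) - 1):-1)[seq_len(height)] / height
  fx <- c(0:floor(width / 2), -(ceiling(width / 2) - 1):-1)[seq_len(width)] / width
  f <- sqrt(outer(fy^2, fx^2, `+`))
  a <- f
  a[f > 0] <- f[f > 0]^(-gamma)
  a[f == 0] <- 0
  a
}

# Impose target amplitudes `amp` on image `x`, keeping x's Fourier phases.
impose_spectrum <- function(x, amp) {
  fx <- fft(x)
  m <- Mod(fx)
  ph <- fx
  nz <- m > 0
  ph[nz] <- fx[nz] / m[nz]
  ph[!nz] <- 0
  Re(fft(amp * ph, inverse = TRUE)) / length(x)
}

#' Structured 1/f image corpus
#'
#' Synthesizes chromatic images whose radially averaged amplitude spectrum
#' falls as `1/f^spectral_exponent` (the hallmark second-order statistic of
#' natural scenes) and whose Fourier phases are structured beyond second
#' order. Each image starts as a random-phase field with the target spectrum;
#' a pointwise signed-square transform (`x |x|`) then concentrates energy
#' into sparse, localized events, and the target amplitude spectrum is
#' re-imposed so higher-order structure lives in the phases alone. Chromatic
#' channels are generated from correlated underlying fields.
#'
#' @param n number of images.
#' @param height,width image size in pixels.
#' @param spectral_exponent exponent of the `1/f` amplitude fall-off
#'   (0 = white).
#' @param chromatic_corr correlation of the underlying channel fields,
#'   in `[-1, 1]`.
#' @param n_channels number of chromatic channels (default 2).
#' @param nonlinearity `"signed_square"` (default) applies the pointwise
#'   transform that creates higher-order structure; `"none"` leaves the
#'   random-phase Gaussian field untouched.
#' @param seed integer seed.
#' @return An [image_corpus] with provenance `"structured"` (or
#'   `"white_noise"` when `spectral_exponent = 0` and `nonlinearity = "none"`).
#' @export
generate_structured_images <- function(n, height = 28, width = 28,
                                       spectral_exponent = 1.0,
                                       chromatic_corr = 0.8,
                                       n_channels = 2,
                                       nonlinearity = c("signed_square", "none"),
                                       seed = 1) {
  n <- check_count(n, "n")
  check_scalar(spectral_exponent, "spectral_exponent", lower = 0)
  if (abs(chromatic_corr) > 1)
    stop("`chromatic_corr` must lie in [-1, 1]")
  nonlinearity <- match.arg(nonlinearity)
  amp <- spectral_amplitude_grid(height, width, spectral_exponent)
  imgs <- local_seed(seed, {
    out <- array(0, dim = c(n, n_channels, height, width))
    for (i in seq_len(n)) {
      base <- matrix(rnorm(height * width), height, width)
      for (c in seq_len(n_channels)) {
        z <- if (c == 1) base else {
          chromatic_corr * base +
            sqrt(1 - chromatic_corr^2) * matrix(rnorm(height * width), height, width)
        }
        g <- impose_spectrum(z, amp)
        if (nonlinearity == "signed_square") {
          g <- g * abs(g)
          g <- impose_spectrum(g, amp)
        }
        out[i, c, , ] <- g
      }
      m <- max(abs(out[i, , , ]))
      if (m > 0) out[i, , , ] <- out[i, , , ] / m
    }
    out
  })
  prov <- if (spectral_exponent == 0 && nonlinearity == "none") "white_noise"
          else "structured"
  image_corpus(imgs, prov)
}

#' White-noise image corpus
#'
#' Gaussian white-noise images, independent across pixels, channels and
#' images, rescaled per image to `[-1, 1]`. The spatially and chromatically
#' unstructured control input for the autoencoder branch.
#'
#' @inheritParams generate_structured_images
#' @return An [image_corpus] with provenance `"white_noise"`.
#' @export
generate_white_noise_images <- function(n, height = 28, width = 28,
                                        n_channels = 2, seed = 1) {
  n <- check_count(n, "n")
  imgs <- local_seed(seed, {
    out <- array(rnorm(n * n_channels * height * width),
                 dim = c(n, n_channels, height, width))
    for (i in seq_len(n)) out[i, , , ] <- out[i, , , ] / max(abs(out[i, , , ]))
    out
  })
  image_corpus(imgs, "white_noise")
}

#' Phase-scramble an image corpus
#'
#' Replaces each image's Fourier phases with the (Hermitian-symmetric) phases
#' of a random real field while preserving the per-channel amplitude spectrum
#' exactly. This destroys statistics beyond second order while keeping the
#' power spectrum; the DC component is left untouched.
#'
#' @param corpus an [image_corpus].
#' @param seed integer seed.
#' @param rescale if `TRUE` (default) every output image is rescaled to
#'   `[-1, 1]`; set to `FALSE` to inspect the raw amplitude-preserving output.
#' @return An [image_corpus] with provenance `"phase_scrambled"`.
#' @export
phase_scramble <- function(corpus, seed = 1, rescale = TRUE) {
  stopifnot(inherits(corpus, "image_corpus"))
  d <- dim(corpus$images)
  if (d[1] < 1) stop("`corpus` must contain at least one image")
  n <- d[1]; nc <- d[2]; h <- d[3]; w <- d[4]
  imgs <- local_seed(seed, {
    out <- array(0, dim = d)
    for (i in seq_len(n)) {
      for (c in seq_len(nc)) {
        x <- matrix(corpus$images[i, c, , ], h, w)
        fx <- fft(x)
        noise <- matrix(rnorm(h * w), h, w)
        fn <- fft(noise)
        mn <- Mod(fn)
        ph <- fn
        nz <- mn > 0
        ph[nz] <- fn[nz] / mn[nz]
        y <- Mod(fx) * ph
        y[1, 1] <- fx[1, 1]          # keep DC: mean luminance is not a phase
        out[i, c, , ] <- Re(fft(y, inverse = TRUE)) / (h * w)
      }
      if (rescale) {
        m <- max(abs(out[i, , , ]))
        if (m > 0) out[i, , , ] <- out[i, , , ] / m
      }
    }
    out
  })
  if (!rescale && max(abs(imgs)) > 1) {
    # container admits only [-1, 1]; hand back a bare structure for inspection
    return(structure(list(images = imgs, provenance = "phase_scrambled"),
                     class = "image_corpus"))
  }
  image_corpus(imgs, "phase_scrambled")
}
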