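# Layout conventions for the convolution engine
#
# Images/frames are handled internally as column-major arrays (H, W, C, B).
# im2col produces a patch matrix with rows ordered (ky, kx, c) -- ky fastest
# -- and columns ordered (oy, ox, b). Filter tensors in user-facing layout
# [n_filters x channel x K x K] (or [... x lag x K x K] for spatio-temporal
# filters) are reshaped into matching matrices so every convolution is a
# single matrix product.

im2col <- function(x, K, pad) {
  d <- dim(x)
  im2col_cpp(as.double(x), d[1], d[2], d[3], d[4], as.integer(K),
             as.integer(pad))
}

col2im <- function(P, H, W, C, B, K, pad) {
  col2im_cpp(P, as.integer(H), as.integer(W), as.integer(C), as.integer(B),
             as.integer(K), as.integer(pad))
}

# Reusable large temporaries for the training loop. Patch matrices reach tens
# of MB; reallocating (and page-faulting) them every mini-batch dominates the
# step cost, so they are checked out of a small pool instead. Each call site
# uses its own tag because two pooled buffers of identical shape can be alive
# at once within one forward/backward pass.
.pool <- new.env(parent = emptyenv())

pool_matrix <- function(nr, nc, tag) {
  key <- paste0(tag, ":", nr, "x", nc)
  b <- .pool[[key]]
  if (is.null(b)) {
    b <- matrix(0, nr, nc)
    .pool[[key]] <- b
  }
  b
}

pool_vector <- function(n, tag) {
  key <- paste0(tag, ":v", n)
  b <- .pool[[key]]
  if (is.null(b)) {
    b <- numeric(n)
    .pool[[key]] <- b
  }
  b
}

# im2col into a pooled buffer. The result is only valid until the next call
# with the same tag; callers must not retain or modify it.
im2col_pooled <- function(x, K, pad, tag) {
  d <- dim(x)
  oh <- d[1] + 2 * pad - K + 1
  ow <- d[2] + 2 * pad - K + 1
  P <- pool_matrix(K * K * d[3], oh * ow * d[4], tag)
  im2col_into(as.double(x), P, d[1], d[2], d[3], d[4], as.integer(K),
              as.integer(pad))
  P
}

col2im_pooled <- function(P, H, W, C, B, K, pad, tag) {
  buf <- pool_vector(H * W * C * B, tag)
  col2im_into(P, buf, as.integer(H), as.integer(W), as.integer(C),
              as.integer(B), as.integer(K), as.integer(pad))
  buf
}

# [nf, C, K, K] <-> nf x (K*K*C) with columns ordered (ky, kx, c)
ws_to_mat <- function(W) matrix(aperm(W, c(1, 3, 4, 2)), nrow = dim(W)[1])

mat_to_ws <- function(M, nf, C, K) {
  aperm(array(M, c(nf, K, K, C)), c(1, 4, 2, 3))
}

# [nf, C, L, K, K] <-> nf x (K*K*C*L) with columns ordered (ky, kx, c, lag)
w3_to_mat <- function(W) matrix(aperm(W, c(1, 4, 5, 2, 3)), nrow = dim(W)[1])

mat_to_w3 <- function(M, nf, C, L, K) {
  aperm(array(M, c(nf, K, K, C, L)), c(1, 4, 5, 2, 3))
}

# Stimulus frames [T, C, H, W] -> internal (H, W, C, T) cache used by the
# training loop and the forward passes.
stim_cache <- function(stimulus) {
  d <- dim(stimulus$frames)
  list(x = aperm(stimulus$frames, c(3, 4, 2, 1)),
       T = d[1], C = d[2], H = d[3], W = d[4])
}
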