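#' Basis set for spatial convolutional filters
#'
#' Container for the orthonormal basis images from which basis-constrained
#' spatial filters are composed. PCA bases are channel-joint
#' (`[k x channel x N x N]`); DCT bases are per-channel gray images
#' (`[k x N x N]`) reused for every chromatic channel.
#'
#' @param basis numeric array (see above).
#' @param kind `"pca"` or `"dct"`.
#' @param ... additional metadata stored on the object (eigenvalues, zig-zag
#'   indices, ...).
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(basis, kind = c("pca", "dct"), ...) {
  kind <- match.arg(kind)
  structure(c(list(basis = basis, kind = kind, k = dim(basis)[1]), list(...)),
            class = "basis_set")
}

# JPEG-style zig-zag traversal of (u, v) frequency indices:
# (0,0),(0,1),(1,0),(2,0),(1,1),(0,2),(0,3),...
zigzag_order <- function(N) {
  out <- matrix(0L, 0, 2)
  for (s in 0:(2 * N - 2)) {
    u <- if (s %% 2 == 1) 0:s else s:0
    v <- s - u
    keep <- u < N & v < N
    out <- rbind(out, cbind(u[keep], v[keep]))
  }
  colnames(out) <- c("u", "v")
  out
}

#' 2D discrete cosine transform basis
#'
#' Returns the first `k` orthonormal 2D-DCT basis images of size `N x N`,
#' ordered by JPEG-style zig-zag index so that low spatial frequencies come
#' first. The normalization \eqn{\alpha(u) = \sqrt{1/N}} for `u = 0` and
#' \eqn{\sqrt{2/N}} otherwise makes the flattened basis orthonormal.
#'
#' @param N side length of the basis images.
#' @param k number of basis images, `1 <= k <= N^2`.
#' @return A [basis_set] of kind `"dct"` with the zig-zag `(u, v)` index pairs
#'   in `$indices`.
#' @export
make_dct_basis <- function(N, k) {
  N <- check_count(N, "N")
  k <- check_count(k, "k")
  if (k > N^2) stop("`k` must be at most N^2")
  zz <- zigzag_order(N)[seq_len(k), , drop = FALSE]
  alpha <- function(u) ifelse(u == 0, sqrt(1 / N), sqrt(2 / N))
  i <- 0:(N - 1)
  basis <- array(0, dim = c(k, N, N))
  for (b in seq_len(k)) {
    u <- zz[b, 1]; v <- zz[b, 2]
    cy <- cos((2 * i + 1) * pi * u / (2 * N))
    cx <- cos((2 * i + 1) * pi * v / (2 * N))
    basis[b, , ] <- alpha(u) * alpha(v) * outer(cy, cx)
  }
  basis_set(basis, "dct", indices = zz, N = N)
}

#' PCA basis from an image corpus
#'
#' Extracts all `patch_size x patch_size` channel-joint patches (stride 1)
#' from the corpus, and returns the top-`k` eigenvectors of the centered
#' patch covariance matrix as basis images, ordered by non-increasing
#' eigenvalue.
#'
#' @param corpus an [image_corpus].
#' @param k number of basis elements.
#' @param patch_size patch side length (default 9, the filter size).
#' @return A [basis_set] of kind `"pca"` carrying `$eigenvalues`. If the
#'   patch covariance has rank below `k`, fewer bases are returned with a
#'   warning.
#' @export
make_pca_basis <- function(corpus, k, patch_size = 9) {
  stopifnot(inherits(corpus, "image_corpus"))
  k <- check_count(k, "k")
  d <- dim(corpus$images)
  n <- d[1]; nc <- d[2]; h <- d[3]; w <- d[4]
  if (h < patch_size || w < patch_size)
    stop("images smaller than the requested patch size")
  x <- aperm(corpus$images, c(3, 4, 2, 1))          # (H, W, C, n)
  P <- im2col_cpp(as.double(x), h, w, nc, n, patch_size, 0L)
  X <- t(P)                                         # patches in rows
  X <- sweep(X, 2, colMeans(X))
  covm <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(covm, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (rank < k) {
    warning(sprintf("patch covariance has rank %d < k = %d; returning %d bases",
                    rank, k, rank))
    k <- rank
  }
  K <- patch_size
  basis <- array(0, dim = c(k, nc, K, K))
  for (b in seq_len(k)) {
    v <- eg$vectors[, b]                            # patch-row order (ky, kx, c)
    basis[b, , , ] <- aperm(array(v, c(K, K, nc)), c(3, 1, 2))
  }
  basis_set(basis, "pca", eigenvalues = eg$values[seq_len(k)], N = K,
            n_channels = nc)
}

#' Compose spatial filters from basis weights
#'
#' Builds the full spatial filter tensor as weighted sums of basis elements.
#' For a PCA (channel-joint) basis, `weights` is `[n_filters x k]`; for a DCT
#' (per-channel) basis, `weights` is `[n_filters x k x n_channels]` and the
#' same gray basis is applied per chromatic channel.
#'
#' @param weights numeric matrix or array of basis weights.
#' @param basis a [basis_set].
#' @param n_channels number of chromatic channels (needed for DCT).
#' @return Filter array `[n_filters x channel x N x N]`.
#' @export
compose_filters_from_basis <- function(weights, basis, n_channels = 2) {
  stopifnot(inherits(basis, "basis_set"))
  k <- basis$k
  if (basis$kind == "pca") {
    if (!is.matrix(weights) || ncol(weights) != k)
      stop("PCA weights must be a [n_filters x k] matrix")
    db <- dim(basis$basis)                          # (k, C, N, N)
    bm <- matrix(basis$basis, nrow = k)
    array(weights %*% bm, dim = c(nrow(weights), db[2], db[3], db[4]))
  } else {
    dw <- dim(weights)
    if (length(dw) != 3L || dw[2] != k || dw[3] != n_channels)
      stop("DCT weights must be a [n_filters x k x n_channels] array")
    N <- dim(basis$basis)[2]
    bm <- matrix(basis$basis, nrow = k)             # k x (N*N)
    out <- array(0, dim = c(dw[1], n_channels, N, N))
    for (c in seq_len(n_channels))
      out[, c, , ] <- array(weights[, , c] %*% bm, dim = c(dw[1], N, N))
    out
  }
}
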