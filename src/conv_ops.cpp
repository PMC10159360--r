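#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix extraction for 2D convolution by matrix multiplication.
//
// Input  x: numeric array dim (H, W, C, B), column-major.
// Output P: matrix (K*K*C) x (OH*OW*B) with OH = H + 2*pad - K + 1.
// Row order:    ky + (kx-1)*K + (c-1)*K*K   (ky fastest)
// Column order: oy + (ox-1)*OH + (b-1)*OH*OW (oy fastest)
// Out-of-range input positions (zero padding) contribute 0.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int B,
                         int K, int pad) {
  const int OH = H + 2 * pad - K + 1;
  const int OW = W + 2 * pad - K + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
  NumericMatrix P(K * K * C, OH * OW * B);
  const double* xp = x.begin();
  double* pp = P.begin();
  const int nrow = K * K * C;
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const int col = oy + ox * OH + b * OH * OW;
        double* dst = pp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* src = xp + ((size_t)b * C + c) * H * W;
          for (int kx = 0; kx < K; ++kx) {
            const int ix = ox + kx - pad;
            const bool xin = ix >= 0 && ix < W;
            for (int ky = 0; ky < K; ++ky) {
              const int iy = oy + ky - pad;
              double v = 0.0;
              if (xin && iy >= 0 && iy < H) v = src[iy + (size_t)ix * H];
              dst[ky + kx * K + c * K * K] = v;
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col_cpp: scatter-add patch columns back into images.
// P has the layout produced by im2col_cpp; returns array dim (H, W, C, B).

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix P, int H, int W, int C, int B,
                         int K, int pad) {
  const int OH = H + 2 * pad - K + 1;
  const int OW = W + 2 * pad - K + 1;
  if (P.nrow() != K * K * C || P.ncol() != OH * OW * B)
    stop("patch matrix dimensions do not match the requested geometry");
  NumericVector x(H * W * C * B);
  double* xp = x.begin();
  const double* pp = P.begin();
  const int nrow = K * K * C;
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const int col = oy + ox * OH + b * OH * OW;
        const double* src = pp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          double* dst = xp + ((size_t)b * C + c) * H * W;
          for (int kx = 0; kx < K; ++kx) {
            const int ix = ox + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < K; ++ky) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= H) continue;
              dst[iy + (size_t)ix * H] += src[ky + kx * K + c * K * K];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, B);
  return x;
}

// In-place Adam update: par, m, v are modified directly (they are private
// optimizer/parameter buffers, never user-visible copies).

// [[Rcpp::export]]
void adam_update_cpp(NumericVector par, NumericVector m, NumericVector v,
                     NumericVector grad, double lr, double beta1,
                     double beta2, double eps, double c1, double c2) {
  const R_xlen_t n = par.size();
  double* p = par.begin(); double* mp = m.begin(); double* vp = v.begin();
  const double* g = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * g[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * g[i] * g[i];
    p[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// Variants of im2col/col2im writing into a caller-provided buffer, so the
// training loop can reuse large temporaries instead of reallocating them.

// [[Rcpp::export]]
void im2col_into(NumericVector x, NumericMatrix P, int H, int W, int C,
                 int B, int K, int pad) {
  const int OH = H + 2 * pad - K + 1;
  const int OW = W + 2 * pad - K + 1;
  if (P.nrow() != K * K * C || P.ncol() != OH * OW * B)
    stop("buffer dimensions do not match the requested geometry");
  const double* xp = x.begin();
  double* pp = P.begin();
  const int nrow = K * K * C;
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const int col = oy + ox * OH + b * OH * OW;
        double* dst = pp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* src = xp + ((size_t)b * C + c) * H * W;
          for (int kx = 0; kx < K; ++kx) {
            const int ix = ox + kx - pad;
            const bool xin = ix >= 0 && ix < W;
            for (int ky = 0; ky < K; ++ky) {
              const int iy = oy + ky - pad;
              double val = 0.0;
              if (xin && iy >= 0 && iy < H) val = src[iy + (size_t)ix * H];
              dst[ky + kx * K + c * K * K] = val;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
void col2im_into(NumericMatrix P, NumericVector x, int H, int W, int C,
                 int B, int K, int pad) {
  const int OH = H + 2 * pad - K + 1;
  const int OW = W + 2 * pad - K + 1;
  if (P.nrow() != K * K * C || P.ncol() != OH * OW * B)
    stop("patch matrix dimensions do not match the requested geometry");
  if (x.size() != (R_xlen_t)H * W * C * B)
    stop("output buffer has the wrong size");
  std::fill(x.begin(), x.end(), 0.0);
  double* xp = x.begin();
  const double* pp = P.begin();
  const int nrow = K * K * C;
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const int col = oy + ox * OH + b * OH * OW;
        const double* src = pp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          double* dst = xp + ((size_t)b * C + c) * H * W;
          for (int kx = 0; kx < K; ++kx) {
            const int ix = ox + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < K; ++ky) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= H) continue;
              dst[iy + (size_t)ix * H] += src[ky + kx * K + c * K * K];
            }
          }
        }
      }
    }
  }
}
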