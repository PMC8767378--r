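// Low-level numeric kernels for the landmark CNN: im2col/col2im lowering of
// 2D convolution to matrix multiplication, max pooling with argmax capture,
// and bilinear resampling. Arrays are H x W x C R arrays (column-major).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_side(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Lower an H x W x C image to a (oh*ow) x (kh*kw*C) patch matrix.
// Column order: (ki, kj, c) fastest over ki, matching the weight layout
// used on the R side. Out-of-bounds taps read zero (zero padding).
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = out_side(H, kh, stride, pad);
  const int ow = out_side(W, kw, stride, pad);
  if (oh < 1 || ow < 1) stop("filter larger than (padded) input");
  arma::mat cols(oh * ow, kh * kw * C, arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = (size_t)c * kh * kw + (size_t)kj * kh + ki;
        double* ccol = cp + col * (size_t)oh * ow;
        const double* xc = xp + (size_t)c * plane;
        // valid output rows a where i = a*stride - pad + ki lies in [0, H)
        const int a0 = std::max(0, (pad - ki + stride - 1) / stride);
        const int a1 = std::min(oh - 1, (H - 1 + pad - ki) / stride);
        if (a1 < a0) continue;
        for (int b = 0; b < ow; ++b) {
          const int j = b * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double* src = xc + (size_t)j * H - pad + ki;
          double* dst = ccol + (size_t)b * oh;
          if (stride == 1) {
            std::memcpy(dst + a0, src + a0, (size_t)(a1 - a0 + 1) * sizeof(double));
          } else {
            for (int a = a0; a <= a1; ++a) dst[a] = src[(size_t)a * stride];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add patch-matrix gradients back to image.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int pad) {
  const int oh = out_side(H, kh, stride, pad);
  const int ow = out_side(W, kw, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  double* xp = x.memptr();
  const double* cp = cols.memptr();
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = (size_t)c * kh * kw + (size_t)kj * kh + ki;
        const double* ccol = cp + col * (size_t)oh * ow;
        double* xc = xp + (size_t)c * plane;
        const int a0 = std::max(0, (pad - ki + stride - 1) / stride);
        const int a1 = std::min(oh - 1, (H - 1 + pad - ki) / stride);
        if (a1 < a0) continue;
        for (int b = 0; b < ow; ++b) {
          const int j = b * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* dst = xc + (size_t)j * H - pad + ki;
          const double* src = ccol + (size_t)b * oh;
          if (stride == 1) {
            for (int a = a0; a <= a1; ++a) dst[a] += src[a];
          } else {
            for (int a = a0; a <= a1; ++a) dst[(size_t)a * stride] += src[a];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling with zero padding. Padded cells never win against any real
// cell because candidates are initialised to -inf and only in-bounds taps
// are considered; a window fully inside padding yields 0.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = out_side(H, k, stride, pad);
  const int ow = out_side(W, k, stride, pad);
  arma::cube out(oh, ow, C);
  arma::icube idx(oh, ow, C);  // linear index into x, -1 if window all-pad
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < ow; ++b) {
      for (int a = 0; a < oh; ++a) {
        double best = -arma::datum::inf;
        long long best_idx = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int j = b * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int i = a * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            const double v = x(i, j, c);
            if (v > best) { best = v; best_idx = (long long)c * H * W + (long long)j * H + i; }
          }
        }
        out(a, b, c) = best_idx < 0 ? 0.0 : best;
        idx(a, b, c) = best_idx;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dout, const arma::icube& idx,
                           int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const arma::sword n = dout.n_elem;
  for (arma::sword t = 0; t < n; ++t) {
    const long long p = idx(t);
    if (p >= 0) dx(p) += dout(t);
  }
  return dx;
}

// Bilinear resize of an H x W x C image to new_h x new_w.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int new_h, int new_w) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(new_h, new_w, C);
  const double sy = new_h > 1 ? (double)(H - 1) / (new_h - 1) : 0.0;
  const double sx = new_w > 1 ? (double)(W - 1) / (new_w - 1) : 0.0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < new_w; ++j) {
      const double fx = j * sx;
      const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, W - 1);
      const double wx = fx - x0;
      for (int i = 0; i < new_h; ++i) {
        const double fy = i * sy;
        const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, H - 1);
        const double wy = fy - y0;
        out(i, j, c) =
          (1 - wy) * ((1 - wx) * x(y0, x0, c) + wx * x(y0, x1, c)) +
          wy       * ((1 - wx) * x(y1, x0, c) + wx * x(y1, x1, c));
      }
    }
  }
  return out;
}
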