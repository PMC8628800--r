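// Hot loops for the minimal CNN framework.
//
// Batch layout: a batch of N feature maps of H x W pixels and C channels is
// an (H*W*C) x N matrix; within a column, channel c occupies the contiguous
// block [c*H*W, (c+1)*H*W) in column-major (h fastest) pixel order.
//
// Convolution uses an im2col patch matrix in "patch-row" orientation,
// (H*W*N) x (9*C): row (n*HW + w*H + h) holds the 3x3 neighbourhood of
// pixel (h, w) of image n; column (c*9 + (dw+1)*3 + (dh+1)) is the channel-c
// sample at offset (dh, dw). This keeps every inner copy contiguous in h.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 3x3 same-padding patch extraction: (H*W*N) x (9*C).
// [[Rcpp::export]]
arma::mat im2col3(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_cols;
  const size_t HW = (size_t)H * W;
  mat P(HW * N, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        double* pc = P.colptr(c * 9 + (dw + 1) * 3 + (dh + 1));
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int len = h1 - h0;
        if (len <= 0) continue;
        for (int n = 0; n < N; ++n) {
          const double* xc = X.colptr(n) + (size_t)c * HW;
          double* pn = pc + (size_t)n * HW;
          for (int w = w0; w < w1; ++w) {
            std::memcpy(pn + (size_t)w * H + h0,
                        xc + (size_t)(w + dw) * H + h0 + dh,
                        len * sizeof(double));
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col3: scatter-add patch gradients back to image layout.
// [[Rcpp::export]]
arma::mat col2im3(const arma::mat& P, int H, int W, int C, int N) {
  const size_t HW = (size_t)H * W;
  mat X(HW * C, N, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const double* pc = P.colptr(c * 9 + (dw + 1) * 3 + (dh + 1));
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        if (h1 <= h0) continue;
        for (int n = 0; n < N; ++n) {
          double* xc = X.colptr(n) + (size_t)c * HW;
          const double* pn = pc + (size_t)n * HW;
          for (int w = w0; w < w1; ++w) {
            double* dst = xc + (size_t)(w + dw) * H + dh;
            const double* src = pn + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  return X;
}

// (HW*N x F) conv output (+ per-filter bias) -> (HW*F x N) batch layout.
// [[Rcpp::export]]
arma::mat fold_fmap(const arma::mat& Z, const arma::vec& b, int HW, int F,
                    int N) {
  mat Y((size_t)HW * F, N);
  for (int f = 0; f < F; ++f) {
    const double* zf = Z.colptr(f);
    const double bf = b[f];
    for (int n = 0; n < N; ++n) {
      double* y = Y.colptr(n) + (size_t)f * HW;
      const double* z = zf + (size_t)n * HW;
      for (int p = 0; p < HW; ++p) y[p] = z[p] + bf;
    }
  }
  return Y;
}

// Inverse layout change of fold_fmap (no bias).
// [[Rcpp::export]]
arma::mat unfold_fmap(const arma::mat& Y, int HW, int F, int N) {
  mat G((size_t)HW * N, F);
  for (int f = 0; f < F; ++f) {
    double* gf = G.colptr(f);
    for (int n = 0; n < N; ++n) {
      std::memcpy(gf + (size_t)n * HW, Y.colptr(n) + (size_t)f * HW,
                  HW * sizeof(double));
    }
  }
  return G;
}

// 2x2 max pooling (stride 2). Returns pooled maps and the 0-based row index
// of each argmax within the input column (ties toward the first in h-then-w
// order, so the result is deterministic).
// [[Rcpp::export]]
Rcpp::List maxpool2(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_cols, Ho = H / 2, Wo = W / 2;
  const size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  mat Y(HWo * C, N);
  umat idx(HWo * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = X.colptr(n);
    double* y = Y.colptr(n);
    uword* id = idx.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = c * HW + (size_t)(2 * wo) * H + 2 * ho;
          double bv = xn[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k) {
            if (xn[cand[k]] > bv) { bv = xn[cand[k]]; best = cand[k]; }
          }
          const size_t o = c * HWo + (size_t)wo * Ho + ho;
          y[o] = bv;
          id[o] = best;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd(const arma::mat& G, const arma::umat& idx,
                       int in_rows) {
  mat dX(in_rows, G.n_cols, fill::zeros);
  for (uword n = 0; n < G.n_cols; ++n) {
    double* d = dX.colptr(n);
    const double* g = G.colptr(n);
    const uword* id = idx.colptr(n);
    for (uword r = 0; r < G.n_rows; ++r) d[id[r]] += g[r];
  }
  return dX;
}

// 2x2 average pooling (stride 2).
// [[Rcpp::export]]
arma::mat avgpool2(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_cols, Ho = H / 2, Wo = W / 2;
  const size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  mat Y(HWo * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = X.colptr(n);
    double* y = Y.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t i = c * HW + (size_t)(2 * wo) * H + 2 * ho;
          y[c * HWo + (size_t)wo * Ho + ho] =
            0.25 * (xn[i] + xn[i + 1] + xn[i + H] + xn[i + H + 1]);
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat avgpool2_bwd(const arma::mat& G, int H, int W, int C) {
  const int N = G.n_cols, Ho = H / 2, Wo = W / 2;
  const size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  mat dX(HW * C, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    double* d = dX.colptr(n);
    const double* g = G.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double v = 0.25 * g[c * HWo + (size_t)wo * Ho + ho];
          const size_t i = c * HW + (size_t)(2 * wo) * H + 2 * ho;
          d[i] += v; d[i + 1] += v; d[i + H] += v; d[i + H + 1] += v;
        }
      }
    }
  }
  return dX;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::mat upsample2(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_cols, Ho = 2 * H;
  const size_t HWo = (size_t)Ho * 2 * W, HW = (size_t)H * W;
  mat Y(HWo * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = X.colptr(n);
    double* y = Y.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const double v = xn[c * HW + (size_t)w * H + h];
          const size_t o = c * HWo + (size_t)(2 * w) * Ho + 2 * h;
          y[o] = v; y[o + 1] = v; y[o + Ho] = v; y[o + Ho + 1] = v;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample2_bwd(const arma::mat& G, int H, int W, int C) {
  // H, W are the *input* (pre-upsampling) dimensions
  const int N = G.n_cols, Ho = 2 * H;
  const size_t HWo = (size_t)Ho * 2 * W, HW = (size_t)H * W;
  mat dX(HW * C, N);
  for (int n = 0; n < N; ++n) {
    double* d = dX.colptr(n);
    const double* g = G.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const size_t o = c * HWo + (size_t)(2 * w) * Ho + 2 * h;
          d[c * HW + (size_t)w * H + h] =
            g[o] + g[o + 1] + g[o + Ho] + g[o + Ho + 1];
        }
      }
    }
  }
  return dX;
}

// ---- rasterizer ----
// Exact area coverage of the EMG envelope field: interval j of the time
// axis carries the vertical span [lo_j, hi_j] (fractions of panel height,
// 0 = top); pixel (r, c) receives the time-weighted overlap of those spans
// with its own box. Resolution-independent by construction.
// [[Rcpp::export]]
arma::mat render_trace(const arma::vec& lo, const arma::vec& hi, int half,
                       int out_px) {
  const int n = lo.n_elem;
  mat img(half, out_px, fill::zeros);
  const double tw = (double)n / out_px;   // signal intervals per pixel column
  for (int c = 0; c < out_px; ++c) {
    const double t0 = (double)c * tw, t1 = (double)(c + 1) * tw;
    const int j0 = (int)std::floor(t0);
    const int j1 = std::min(n, (int)std::ceil(t1));
    for (int j = j0; j < j1; ++j) {
      const double w = std::min(t1, (double)j + 1) - std::max(t0, (double)j);
      if (w <= 0) continue;
      const double ylo = lo[j] * half, yhi = hi[j] * half;
      const int r0 = std::max(0, (int)std::floor(ylo));
      const int r1 = std::min(half - 1, (int)std::floor(yhi));
      for (int r = r0; r <= r1; ++r) {
        const double ov = std::min(yhi, (double)r + 1) -
          std::max(ylo, (double)r);
        if (ov > 0) img(r, c) += (w / tw) * ov;
      }
    }
  }
  return clamp(img, 0.0, 1.0);
}
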