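// Patch-matrix kernels for 3x3 same-padding convolutions on [H, W, B, C]
// arrays. These are pure data movement (the matrix products stay in R/BLAS);
// compiled because R-level 4D slicing dominates training time otherwise.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// x: [H, W, B, C] flattened column-major. Returns [(H*W*B) x (9*C)] with
// out[h + H*(w + W*b), k + 9*c] = x[h + di_k, w + dj_k, b, c] (zero-padded),
// offsets k enumerated with di fastest: (di, dj) in column-major order.
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int B, int C) {
  R_xlen_t HWB = (R_xlen_t)H * W * B;
  NumericMatrix out(HWB, 9 * C);
  const double* px = x.begin();
  double* po = out.begin();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      int h0 = std::max(0, -di), h1 = std::min(H, H - di);
      if (h1 <= h0) { ++k; continue; }
      for (int c = 0; c < C; ++c) {
        const double* src = px + HWB * c;
        double* dst = po + HWB * (k + 9 * (R_xlen_t)c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            int wj = w + dj;
            if (wj < 0 || wj >= W) continue;
            const double* s = src + (h0 + di) + (R_xlen_t)H * (wj + (R_xlen_t)W * b);
            double* d = dst + h0 + (R_xlen_t)H * (w + (R_xlen_t)W * b);
            std::memcpy(d, s, sizeof(double) * (h1 - h0));
          }
        }
      }
      ++k;
    }
  }
  return out;
}

// Adjoint of im2col3_cpp: scatter-add patch gradients back to [H, W, B, C].
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix dxp, int H, int W, int B, int C) {
  R_xlen_t HWB = (R_xlen_t)H * W * B;
  NumericVector dx(HWB * C);
  const double* pp = dxp.begin();
  double* pd = dx.begin();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      int h0 = std::max(0, -di), h1 = std::min(H, H - di);
      if (h1 <= h0) { ++k; continue; }
      for (int c = 0; c < C; ++c) {
        const double* src = pp + HWB * (k + 9 * (R_xlen_t)c);
        double* dst = pd + HWB * c;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            int wj = w + dj;
            if (wj < 0 || wj >= W) continue;
            double* d = dst + (h0 + di) + (R_xlen_t)H * (wj + (R_xlen_t)W * b);
            const double* s = src + h0 + (R_xlen_t)H * (w + (R_xlen_t)W * b);
            for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
          }
        }
      }
      ++k;
    }
  }
  return dx;
}

#include <R_ext/BLAS.h>
#include <vector>

// Fused 3x3 conv forward: builds the patch matrix and runs the BLAS gemm in
// one call. Returns y (HWB x Cout) and the patch matrix (cached for backward).
// [[Rcpp::export]]
List conv3_fwd_cpp(NumericVector x, int H, int W, int B, int C,
                   NumericMatrix Wm, NumericVector bias) {
  R_xlen_t HWB = (R_xlen_t)H * W * B;
  int K = 9 * C, Cout = Wm.ncol();
  NumericMatrix xp(no_init(HWB, K));
  std::fill(xp.begin(), xp.end(), 0.0);
  const double* px = x.begin();
  double* po = xp.begin();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      int h0 = std::max(0, -di), h1 = std::min(H, H - di);
      if (h1 > h0) {
        for (int c = 0; c < C; ++c) {
          const double* src = px + HWB * c;
          double* dst = po + HWB * (k + 9 * (R_xlen_t)c);
          for (int b = 0; b < B; ++b)
            for (int w = 0; w < W; ++w) {
              int wj = w + dj;
              if (wj < 0 || wj >= W) continue;
              std::memcpy(dst + h0 + (R_xlen_t)H * (w + (R_xlen_t)W * b),
                          src + (h0 + di) + (R_xlen_t)H * (wj + (R_xlen_t)W * b),
                          sizeof(double) * (h1 - h0));
            }
        }
      }
      ++k;
    }
  }
  NumericMatrix y(no_init(HWB, Cout));
  // y = xp %*% Wm
  const double one = 1.0, zero = 0.0;
  int m = (int)HWB, kk = K, n = Cout;
  F77_CALL(dgemm)("N", "N", &m, &n, &kk, &one, xp.begin(), &m,
                  Wm.begin(), &kk, &zero, y.begin(), &m FCONE FCONE);
  for (int j = 0; j < Cout; ++j) {
    double bj = bias[j];
    double* col = y.begin() + HWB * j;
    for (R_xlen_t i = 0; i < HWB; ++i) col[i] += bj;
  }
  return List::create(_["y"] = y, _["xp"] = xp);
}

// Fused backward: dW = xp^T dy, db = colSums(dy), dx = col2im(dy Wm^T).
// The patch-gradient buffer lives only inside this call.
// [[Rcpp::export]]
List conv3_bwd_cpp(NumericMatrix dy, NumericMatrix xp, NumericMatrix Wm,
                   int H, int W, int B, int C) {
  R_xlen_t HWB = (R_xlen_t)H * W * B;
  int K = 9 * C, Cout = Wm.ncol();
  const double one = 1.0, zero = 0.0;
  int m = (int)HWB;
  NumericMatrix dW(no_init(K, Cout));
  // dW = xp^T (HWB x K)^T %*% dy (HWB x Cout)
  F77_CALL(dgemm)("T", "N", &K, &Cout, &m, &one, xp.begin(), &m,
                  dy.begin(), &m, &zero, dW.begin(), &K FCONE FCONE);
  NumericVector db(Cout);
  for (int j = 0; j < Cout; ++j) {
    const double* col = dy.begin() + HWB * j;
    double s = 0;
    for (R_xlen_t i = 0; i < HWB; ++i) s += col[i];
    db[j] = s;
  }
  // dxp = dy %*% Wm^T  (HWB x K), scratch buffer outside R's heap
  std::vector<double> dxp((size_t)HWB * K);
  F77_CALL(dgemm)("N", "T", &m, &K, &Cout, &one, dy.begin(), &m,
                  Wm.begin(), &K, &zero, dxp.data(), &m FCONE FCONE);
  NumericVector dx(HWB * C);
  double* pd = dx.begin();
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      int h0 = std::max(0, -di), h1 = std::min(H, H - di);
      if (h1 > h0) {
        for (int c = 0; c < C; ++c) {
          const double* src = dxp.data() + HWB * (k + 9 * (size_t)c);
          double* dst = pd + HWB * c;
          for (int b = 0; b < B; ++b)
            for (int w = 0; w < W; ++w) {
              int wj = w + dj;
              if (wj < 0 || wj >= W) continue;
              double* d = dst + (h0 + di) + (R_xlen_t)H * (wj + (R_xlen_t)W * b);
              const double* s = src + h0 + (R_xlen_t)H * (w + (R_xlen_t)W * b);
              for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
            }
        }
      }
      ++k;
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
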