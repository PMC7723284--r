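// Hot loops of the CNN engine: im2col gather / col2im scatter for 3x3
// same-padded convolution, 2x2 average pooling, and the leaky ReLU, all
// on the flat activation layout (H*W*N rows, pixel fastest within
// sample; channels as columns).  Matrix products stay in R's BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// G column for channel c (0-based) and kernel offset (ki, kj) is
// c * 9 + ki + 3 * kj, matching the weight-matrix row order used on the
// R side.  Out-of-grid taps stay zero (same padding).
// [[Rcpp::export]]
NumericMatrix im2col_m(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int HW = H * W;
  NumericMatrix G(HW * N, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int o = ki + 3 * kj;
        const int di = ki - 1, dj = kj - 1;
        double* gcol = &G(0, c * 9 + o);
        for (int n = 0; n < N; ++n) {
          const double* xs = xc + (R_xlen_t)n * HW;
          double* gd = gcol + (R_xlen_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj;
            if (js < 0 || js >= W) continue;
            const double* xcol = xs + (R_xlen_t)js * H;
            double* gpix = gd + (R_xlen_t)j * H;
            const int i0 = (di < 0) ? 1 : 0;
            const int i1 = (di > 0) ? H - 1 : H;
            for (int i = i0; i < i1; ++i) gpix[i] = xcol[i + di];
          }
        }
      }
    }
  }
  return G;
}

// Adjoint of im2col_m: scatter-add the 9C gathered columns back onto the
// C input channels.
// [[Rcpp::export]]
NumericMatrix col2im_m(const NumericMatrix& dG, int H, int W, int N, int C) {
  const int HW = H * W;
  NumericMatrix dX(HW * N, C);
  for (int c = 0; c < C; ++c) {
    double* dxc = &dX(0, c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int o = ki + 3 * kj;
        const int di = ki - 1, dj = kj - 1;
        const double* gcol = &dG(0, c * 9 + o);
        for (int n = 0; n < N; ++n) {
          const double* gs = gcol + (R_xlen_t)n * HW;
          double* dxd = dxc + (R_xlen_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj;
            if (js < 0 || js >= W) continue;
            double* dxcol = dxd + (R_xlen_t)js * H;
            const double* gpix = gs + (R_xlen_t)j * H;
            const int i0 = (di < 0) ? 1 : 0;
            const int i1 = (di > 0) ? H - 1 : H;
            for (int i = i0; i < i1; ++i) dxcol[i + di] += gpix[i];
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 average pooling, stride 2 (H and W even).
// [[Rcpp::export]]
NumericMatrix pool2_fwd(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int HW = H * W, H2 = H / 2, W2 = W / 2, HW2 = H2 * W2;
  NumericMatrix Y(HW2 * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* yc = &Y(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xs = xc + (R_xlen_t)n * HW;
      double* ys = yc + (R_xlen_t)n * HW2;
      for (int j = 0; j < W2; ++j) {
        const double* c0 = xs + (R_xlen_t)(2 * j) * H;
        const double* c1 = xs + (R_xlen_t)(2 * j + 1) * H;
        double* yj = ys + (R_xlen_t)j * H2;
        for (int i = 0; i < H2; ++i) {
          yj[i] = (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]) / 4.0;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix pool2_bwd(const NumericMatrix& dY, int H, int W, int N) {
  const int C = dY.ncol();
  const int HW = H * W, H2 = H / 2, W2 = W / 2, HW2 = H2 * W2;
  NumericMatrix dX(HW * N, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dY(0, c);
    double* dxc = &dX(0, c);
    for (int n = 0; n < N; ++n) {
      const double* dys = dyc + (R_xlen_t)n * HW2;
      double* dxs = dxc + (R_xlen_t)n * HW;
      for (int j = 0; j < W2; ++j) {
        double* c0 = dxs + (R_xlen_t)(2 * j) * H;
        double* c1 = dxs + (R_xlen_t)(2 * j + 1) * H;
        const double* dyj = dys + (R_xlen_t)j * H2;
        for (int i = 0; i < H2; ++i) {
          const double q = dyj[i] / 4.0;
          c0[2 * i] = q;
          c0[2 * i + 1] = q;
          c1[2 * i] = q;
          c1[2 * i + 1] = q;
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
NumericMatrix leaky_fwd_cpp(const NumericMatrix& X, double slope) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  const double* x = X.begin();
  double* y = Y.begin();
  for (R_xlen_t k = 0; k < n; ++k) y[k] = x[k] > 0 ? x[k] : slope * x[k];
  return Y;
}

// [[Rcpp::export]]
NumericMatrix leaky_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                            double slope) {
  NumericMatrix dX(X.nrow(), X.ncol());
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  const double* dy = dY.begin();
  const double* x = X.begin();
  double* dx = dX.begin();
  for (R_xlen_t k = 0; k < n; ++k) dx[k] = x[k] > 0 ? dy[k] : slope * dy[k];
  return dX;
}
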