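// Strided 3D convolution kernels: per-kernel-offset patch gather (memcpy of
// contiguous x-runs) followed by BLAS GEMM.  Layout matches the R side:
// feature maps are (nx, ny, nz, N, C) column-major arrays; weight matrices
// are (k^3*C_in x C_out) with the rows of kernel offset o (x fastest) in
// block o*C_in .. o*C_in+C_in-1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void gather_offset(const double* xpad, arma::mat& sub,
                                 int px, int py, int pz, int N, int C,
                                 int ox, int oy, int oz, int stride,
                                 int dx, int dy, int dz) {
  const long V = (long)ox * oy * oz;
  for (int c = 0; c < C; ++c) {
    double* col = sub.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int z = 0; z < oz; ++z) {
        for (int y = 0; y < oy; ++y) {
          const double* src = xpad + dx +
            (long)px * ((y * stride + dy) +
            (long)py * ((z * stride + dz) + (long)pz * (n + (long)N * c)));
          double* dst = col + (long)ox * (y + (long)oy * z) + V * n;
          if (stride == 1) {
            std::memcpy(dst, src, sizeof(double) * ox);
          } else {
            for (int x = 0; x < ox; ++x) dst[x] = src[(long)x * stride];
          }
        }
      }
    }
  }
}

static inline void scatter_offset(double* dxpad, const arma::mat& dsub,
                                  int px, int py, int pz, int N, int C,
                                  int ox, int oy, int oz, int stride,
                                  int dx, int dy, int dz) {
  const long V = (long)ox * oy * oz;
  for (int c = 0; c < C; ++c) {
    const double* col = dsub.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int z = 0; z < oz; ++z) {
        for (int y = 0; y < oy; ++y) {
          double* dst = dxpad + dx +
            (long)px * ((y * stride + dy) +
            (long)py * ((z * stride + dz) + (long)pz * (n + (long)N * c)));
          const double* src = col + (long)ox * (y + (long)oy * z) + V * n;
          if (stride == 1) {
            for (int x = 0; x < ox; ++x) dst[x] += src[x];
          } else {
            for (int x = 0; x < ox; ++x) dst[(long)x * stride] += src[x];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const NumericVector& xpad, const IntegerVector& pdim,
                        int N, int C, const arma::mat& W, int k, int stride) {
  const int px = pdim[0], py = pdim[1], pz = pdim[2];
  const int ox = (px - k) / stride + 1;
  const int oy = (py - k) / stride + 1;
  const int oz = (pz - k) / stride + 1;
  const long V = (long)ox * oy * oz;
  arma::mat Y(V * N, W.n_cols, arma::fill::zeros);
  arma::mat sub(V * N, C);
  int o = 0;
  for (int dz = 0; dz < k; ++dz)
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx, ++o) {
        gather_offset(REAL(xpad), sub, px, py, pz, N, C, ox, oy, oz, stride,
                      dx, dy, dz);
        Y += sub * W.rows(o * C, o * C + C - 1);
      }
  return Y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const NumericVector& xpad, const IntegerVector& pdim,
                   int N, int C, const arma::mat& dY, const arma::mat& W,
                   int k, int stride) {
  const int px = pdim[0], py = pdim[1], pz = pdim[2];
  const int ox = (px - k) / stride + 1;
  const int oy = (py - k) / stride + 1;
  const int oz = (pz - k) / stride + 1;
  const long V = (long)ox * oy * oz;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  NumericVector dxpad((long)px * py * pz * N * C);
  arma::mat sub(V * N, C);
  int o = 0;
  for (int dz = 0; dz < k; ++dz)
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx, ++o) {
        gather_offset(REAL(xpad), sub, px, py, pz, N, C, ox, oy, oz, stride,
                      dx, dy, dz);
        dW.rows(o * C, o * C + C - 1) = sub.t() * dY;
        arma::mat dsub = dY * W.rows(o * C, o * C + C - 1).t();
        scatter_offset(REAL(dxpad), dsub, px, py, pz, N, C, ox, oy, oz,
                       stride, dx, dy, dz);
      }
  return List::create(Named("dW") = dW, Named("dxpad") = dxpad);
}
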