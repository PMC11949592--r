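// Low-level kernels for the 3D convolutional branch: in-place im2col for
// 3x3x3 stride-1 convolutions with zero padding (workspaces are preallocated
// on the R side and reused across subjects), and 2x2x2 stride-2 max pooling.
// Matrix products run in R through BLAS; the backward input gradient uses
// the flipped-kernel convolution identity on the R side.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Fill P (nvox x k^3*C) with patches of x (d1,d2,d3,C); column index
// = c * k^3 + (kx + k*ky + k^2*kz). Every element is written.
// [[Rcpp::export]]
void im2col_fill(NumericMatrix P, NumericVector x, IntegerVector dims, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  const int k3 = k * k * k;
  const int pad = (k - 1) / 2;
  if (P.nrow() != nvox || P.ncol() != (R_xlen_t)k3 * C)
    stop("im2col_fill: workspace shape mismatch");
  const double *px = x.begin();
  double *pP = P.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (R_xlen_t)c * nvox;
    for (int kz = 0; kz < k; ++kz) {
      const int dz = kz - pad;
      for (int ky = 0; ky < k; ++ky) {
        const int dy = ky - pad;
        for (int kx = 0; kx < k; ++kx) {
          const int dx = kx - pad;
          const int col = c * k3 + kx + k * ky + k * k * kz;
          double *pout = pP + (R_xlen_t)col * nvox;
          for (int i3 = 0; i3 < d3; ++i3) {
            const int j3 = i3 + dz;
            const bool ok3 = (j3 >= 0 && j3 < d3);
            for (int i2 = 0; i2 < d2; ++i2) {
              const int j2 = i2 + dy;
              double *row0 = pout + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
              if (!ok3 || j2 < 0 || j2 >= d2) {
                std::memset(row0, 0, sizeof(double) * d1);
                continue;
              }
              const double *src = xc + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
              const int lo = (dx < 0) ? -dx : 0;
              const int hi = (dx > 0) ? d1 - dx : d1;
              if (lo > 0) std::memset(row0, 0, sizeof(double) * lo);
              if (hi > lo)
                std::memcpy(row0 + lo, src + lo + dx, sizeof(double) * (hi - lo));
              if (hi < d1) std::memset(row0 + hi, 0, sizeof(double) * (d1 - hi));
            }
          }
        }
      }
    }
  }
}

// 2x2x2 stride-2 max pooling with argmax bookkeeping (1-based linear indices
// into the input, for the backward scatter). Trailing odd slices are dropped.
// [[Rcpp::export]]
List maxpool3d_forward(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const R_xlen_t nout = (R_xlen_t)e1 * e2 * e3 * C;
  NumericVector y(nout);
  IntegerVector idx(nout);
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t base_c = (R_xlen_t)c * d1 * d2 * d3;
    for (int i3 = 0; i3 < e3; ++i3) {
      for (int i2 = 0; i2 < e2; ++i2) {
        for (int i1 = 0; i1 < e1; ++i1) {
          double best = R_NegInf;
          R_xlen_t best_ix = 0;
          for (int z = 0; z < 2; ++z)
            for (int yoff = 0; yoff < 2; ++yoff)
              for (int xoff = 0; xoff < 2; ++xoff) {
                const R_xlen_t ix = base_c +
                  (2 * i1 + xoff) +
                  (R_xlen_t)d1 * ((2 * i2 + yoff) + (R_xlen_t)d2 * (2 * i3 + z));
                const double v = px[ix];
                if (v > best) { best = v; best_ix = ix; }
              }
          y[o] = best;
          idx[o] = (int)(best_ix + 1);
          ++o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(e1, e2, e3, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}
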