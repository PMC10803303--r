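// Hot numerical kernels for the miniature 3D networks.
// Layout convention: a C-channel volume of dims (nx, ny, nz) is a numeric
// vector in R array order, x fastest, channel slowest: idx = x + nx*(y + ny*(z + nz*c)).
//
// Convolutions use an im2col in (voxels x taps) orientation so that every
// fill/read streams contiguously down a column, blocked over output
// z-slabs to bound the working set; the GEMMs then run on tall skinny
// matrices in their natural layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int pad, int k, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill colt (chunk_vox x cin*k^3) for output voxels in z-slab [z0, z1).
static void im2col_chunk(const double *x, int nx, int ny, int nz, int cin,
                         int k, int stride, int pad,
                         int ox, int oy, int z0, int z1, arma::mat &colt) {
  const int kk = k * k * k;
  const arma::uword slab = (arma::uword)ox * oy * (z1 - z0);
  for (int c = 0; c < cin; ++c) {
    const double *xc = x + (size_t)nx * ny * nz * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          double *col = colt.colptr(c * kk + kx + k * (ky + k * kz));
          arma::uword r = 0;
          for (int z = z0; z < z1; ++z) {
            const int iz = z * stride + kz - pad;
            const bool zok = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              const bool yok = zok && iy >= 0 && iy < ny;
              if (!yok) {
                for (int xo = 0; xo < ox; ++xo, ++r) col[r] = 0.0;
                continue;
              }
              const double *row = xc + (size_t)nx * (iy + (size_t)ny * iz);
              if (stride == 1) {
                const int ix0 = kx - pad;  // input x for xo = 0
                for (int xo = 0; xo < ox; ++xo, ++r) {
                  const int ix = ix0 + xo;
                  col[r] = (ix >= 0 && ix < nx) ? row[ix] : 0.0;
                }
              } else {
                for (int xo = 0; xo < ox; ++xo, ++r) {
                  const int ix = xo * stride + kx - pad;
                  col[r] = (ix >= 0 && ix < nx) ? row[ix] : 0.0;
                }
              }
            }
          }
          (void)slab;
        }
  }
}

// Scatter-add dcolt back into dx over the same slab (adjoint of im2col_chunk).
static void col2im_chunk(const arma::mat &dcolt, double *dx, int nx, int ny,
                         int nz, int cin, int k, int stride, int pad,
                         int ox, int oy, int z0, int z1) {
  const int kk = k * k * k;
  for (int c = 0; c < cin; ++c) {
    double *xc = dx + (size_t)nx * ny * nz * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const double *col = dcolt.colptr(c * kk + kx + k * (ky + k * kz));
          arma::uword r = 0;
          for (int z = z0; z < z1; ++z) {
            const int iz = z * stride + kz - pad;
            const bool zok = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              const bool yok = zok && iy >= 0 && iy < ny;
              if (!yok) { r += ox; continue; }
              double *row = xc + (size_t)nx * (iy + (size_t)ny * iz);
              for (int xo = 0; xo < ox; ++xo, ++r) {
                const int ix = xo * stride + kx - pad;
                if (ix >= 0 && ix < nx) row[ix] += col[r];
              }
            }
          }
        }
  }
}

static int chunk_rows(int ox, int oy, int taps) {
  // keep the chunk matrix around ~8 MB
  double target = 8.0 * 1024 * 1024 / 8.0 / taps;
  int zc = (int)(target / ((double)ox * oy));
  if (zc < 1) zc = 1;
  return zc;
}

// Forward 3D convolution. W: (out_ch) x (in_ch*k^3), b: out_ch.
// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector dims, int cin,
                            NumericMatrix W, NumericVector b,
                            int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dim(nx, pad, k, stride);
  const int oy = out_dim(ny, pad, k, stride);
  const int oz = out_dim(nz, pad, k, stride);
  const int cout = W.nrow();
  const int taps = cin * k * k * k;
  const arma::uword nvox = (arma::uword)ox * oy * oz;
  arma::mat Wm(W.begin(), cout, taps, false);
  arma::mat Wt = Wm.t();                       // taps x cout
  NumericVector out((size_t)nvox * cout);
  double *op = REAL(out);
  const int zc = chunk_rows(ox, oy, taps);
  arma::mat colt;
  for (int z0 = 0; z0 < oz; z0 += zc) {
    const int z1 = std::min(z0 + zc, oz);
    const arma::uword rows = (arma::uword)ox * oy * (z1 - z0);
    colt.set_size(rows, taps);
    im2col_chunk(REAL(x), nx, ny, nz, cin, k, stride, pad, ox, oy, z0, z1, colt);
    arma::mat Y = colt * Wt;                   // rows x cout
    for (int c = 0; c < cout; ++c) {
      double *dst = op + (size_t)nvox * c + (size_t)ox * oy * z0;
      std::memcpy(dst, Y.colptr(c), rows * sizeof(double));
      const double bc = b[c];
      if (bc != 0) for (arma::uword r = 0; r < rows; ++r) dst[r] += bc;
    }
  }
  // add bias even when zero chunks skipped bias? handled above per chunk
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// Backward pass: returns list(dx, dW, db).
// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector dims, int cin,
                   NumericMatrix W, NumericVector dy,
                   int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dim(nx, pad, k, stride);
  const int oy = out_dim(ny, pad, k, stride);
  const int oz = out_dim(nz, pad, k, stride);
  const int cout = W.nrow();
  const int taps = cin * k * k * k;
  const arma::uword nvox = (arma::uword)ox * oy * oz;
  arma::mat Wm(W.begin(), cout, taps, false);
  arma::mat dWt(taps, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((size_t)nx * ny * nz * cin);
  const double *dyp = REAL(dy);
  const int zc = chunk_rows(ox, oy, taps);
  arma::mat colt, dYc;
  for (int z0 = 0; z0 < oz; z0 += zc) {
    const int z1 = std::min(z0 + zc, oz);
    const arma::uword rows = (arma::uword)ox * oy * (z1 - z0);
    dYc.set_size(rows, cout);
    for (int c = 0; c < cout; ++c)
      std::memcpy(dYc.colptr(c), dyp + (size_t)nvox * c + (size_t)ox * oy * z0,
                  rows * sizeof(double));
    colt.set_size(rows, taps);
    im2col_chunk(REAL(x), nx, ny, nz, cin, k, stride, pad, ox, oy, z0, z1, colt);
    dWt += colt.t() * dYc;
    db += arma::sum(dYc, 0).t();
    arma::mat dcolt = dYc * Wm;                // rows x taps
    col2im_chunk(dcolt, REAL(dx), nx, ny, nz, cin, k, stride, pad,
                 ox, oy, z0, z1);
  }
  arma::mat dW = dWt.t();
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(dW.n_rows, dW.n_cols, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

struct AxisTap { int i0, i1; double w1; };

static std::vector<AxisTap> taps_of(const NumericVector &coord, int n) {
  std::vector<AxisTap> t(coord.size());
  for (int j = 0; j < coord.size(); ++j) {
    double c = coord[j];
    if (c < 0) c = 0;
    if (c > n - 1) c = n - 1;
    int i0 = (int)std::floor(c);
    if (i0 > n - 2) i0 = n - 2;
    if (i0 < 0) i0 = 0;
    t[j].i0 = i0;
    t[j].i1 = (n == 1) ? 0 : i0 + 1;
    t[j].w1 = (n == 1) ? 0.0 : c - i0;
  }
  return t;
}

// Separable trilinear gather at the input coordinates cx, cy, cz (0-based,
// clamped to the grid). Output dims = lengths of the coordinate vectors.
// [[Rcpp::export]]
NumericVector resize3d_fw_cpp(NumericVector x, IntegerVector dims, int cin,
                              NumericVector cx, NumericVector cy, NumericVector cz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = cx.size(), oy = cy.size(), oz = cz.size();
  std::vector<AxisTap> tx = taps_of(cx, nx), ty = taps_of(cy, ny), tz = taps_of(cz, nz);
  NumericVector out((size_t)ox * oy * oz * cin);
  for (int c = 0; c < cin; ++c) {
    const double *xc = REAL(x) + (size_t)nx * ny * nz * c;
    double *oc = REAL(out) + (size_t)ox * oy * oz * c;
    size_t o = 0;
    for (int z = 0; z < oz; ++z) {
      const AxisTap &az = tz[z];
      for (int y = 0; y < oy; ++y) {
        const AxisTap &ay = ty[y];
        const double *p00 = xc + (size_t)nx * (ay.i0 + (size_t)ny * az.i0);
        const double *p10 = xc + (size_t)nx * (ay.i1 + (size_t)ny * az.i0);
        const double *p01 = xc + (size_t)nx * (ay.i0 + (size_t)ny * az.i1);
        const double *p11 = xc + (size_t)nx * (ay.i1 + (size_t)ny * az.i1);
        const double wy1 = ay.w1, wz1 = az.w1;
        const double w00 = (1 - wy1) * (1 - wz1), w10 = wy1 * (1 - wz1);
        const double w01 = (1 - wy1) * wz1, w11 = wy1 * wz1;
        for (int xo = 0; xo < ox; ++xo, ++o) {
          const AxisTap &ax = tx[xo];
          const double a0 = w00 * p00[ax.i0] + w10 * p10[ax.i0] +
                            w01 * p01[ax.i0] + w11 * p11[ax.i0];
          const double a1 = w00 * p00[ax.i1] + w10 * p10[ax.i1] +
                            w01 * p01[ax.i1] + w11 * p11[ax.i1];
          oc[o] = (1 - ax.w1) * a0 + ax.w1 * a1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cin);
  return out;
}

// Adjoint of resize3d_fw_cpp: scatter output-gradients back to the input grid.
// [[Rcpp::export]]
NumericVector resize3d_bw_cpp(NumericVector dy, IntegerVector dims, int cin,
                              NumericVector cx, NumericVector cy, NumericVector cz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = cx.size(), oy = cy.size(), oz = cz.size();
  std::vector<AxisTap> tx = taps_of(cx, nx), ty = taps_of(cy, ny), tz = taps_of(cz, nz);
  NumericVector dx((size_t)nx * ny * nz * cin);
  for (int c = 0; c < cin; ++c) {
    double *xc = REAL(dx) + (size_t)nx * ny * nz * c;
    const double *gc = REAL(dy) + (size_t)ox * oy * oz * c;
    size_t o = 0;
    for (int z = 0; z < oz; ++z) {
      const AxisTap &az = tz[z];
      for (int y = 0; y < oy; ++y) {
        const AxisTap &ay = ty[y];
        double *p00 = xc + (size_t)nx * (ay.i0 + (size_t)ny * az.i0);
        double *p10 = xc + (size_t)nx * (ay.i1 + (size_t)ny * az.i0);
        double *p01 = xc + (size_t)nx * (ay.i0 + (size_t)ny * az.i1);
        double *p11 = xc + (size_t)nx * (ay.i1 + (size_t)ny * az.i1);
        const double wy1 = ay.w1, wz1 = az.w1;
        const double w00 = (1 - wy1) * (1 - wz1), w10 = wy1 * (1 - wz1);
        const double w01 = (1 - wy1) * wz1, w11 = wy1 * wz1;
        for (int xo = 0; xo < ox; ++xo, ++o) {
          const AxisTap &ax = tx[xo];
          const double g = gc[o];
          if (g == 0) continue;
          const double g0 = g * (1 - ax.w1), g1 = g * ax.w1;
          p00[ax.i0] += w00 * g0; p00[ax.i1] += w00 * g1;
          p10[ax.i0] += w10 * g0; p10[ax.i1] += w10 * g1;
          p01[ax.i0] += w01 * g0; p01[ax.i1] += w01 * g1;
          p11[ax.i0] += w11 * g0; p11[ax.i1] += w11 * g1;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return dx;
}
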