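// Low-level dense kernels for the 3D segmentation pipeline.
//
// Array convention (matches the R side): volumes are column-major with
// dim = c(X, Y, Z) or c(X, Y, Z, C); axis 0 = superior-inferior,
// axis 1 = anterior-posterior, axis 2 = right-left; channel slowest.
// Convolutions are "same" with zero padding (k odd), stride 1.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword vidx(int x, int y, int z, int X, int Y) {
  return (arma::uword)x + (arma::uword)X * ((arma::uword)y + (arma::uword)Y * (arma::uword)z);
}

// The toolchain's baseline ISA is conservative; the convolution inner
// loops are compiled additionally for wider vector units and dispatched
// at load time (falls back to the default clone on older CPUs).
#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("arch=x86-64-v4", "arch=x86-64-v3", "default")))
#else
#define HOT_CLONES
#endif

// Accumulate dst(v) += w * src(v + o) over the in-range region; both
// volumes have dims (X, Y, Z). Inner loop is contiguous on both sides.
HOT_CLONES
static void shift_axpy(double* __restrict dst, const double* __restrict src,
                       double w, int ox, int oy, int oz, int X, int Y, int Z) {
  const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
  const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
  const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
  const int n = x1 - x0;
  if (n <= 0) return;
  for (int z = z0; z < z1; ++z) {
    for (int y = y0; y < y1; ++y) {
      double* __restrict d = dst + vidx(x0, y, z, X, Y);
      const double* __restrict s = src + vidx(x0 + ox, y + oy, z + oz, X, Y);
      for (int i = 0; i < n; ++i) d[i] += w * s[i];
    }
  }
}

// Dot product sum_v a(v) * b(v + o) over the in-range region.
HOT_CLONES
static double shift_dot(const double* __restrict a, const double* __restrict b,
                        int ox, int oy, int oz, int X, int Y, int Z) {
  const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
  const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
  const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
  const int n = x1 - x0;
  double acc = 0.0;
  if (n <= 0) return acc;
  for (int z = z0; z < z1; ++z) {
    for (int y = y0; y < y1; ++y) {
      const double* __restrict pa = a + vidx(x0, y, z, X, Y);
      const double* __restrict pb = b + vidx(x0 + ox, y + oy, z + oz, X, Y);
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
      int i = 0;
      for (; i + 4 <= n; i += 4) {
        s0 += pa[i] * pb[i];
        s1 += pa[i + 1] * pb[i + 1];
        s2 += pa[i + 2] * pb[i + 2];
        s3 += pa[i + 3] * pb[i + 3];
      }
      for (; i < n; ++i) s0 += pa[i] * pb[i];
      acc += (s0 + s1) + (s2 + s3);
    }
  }
  return acc;
}

// Copy one channel into a zero-padded (X+2, Y+2, Z+2) scratch volume so
// the 27-tap stencil needs no bounds checks.
static void pad_channel(const double* src, double* dst, int X, int Y, int Z) {
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  std::fill(dst, dst + (arma::uword)Xp * Yp * Zp, 0.0);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      std::copy(src + vidx(0, y, z, X, Y), src + vidx(0, y, z, X, Y) + X,
                dst + (arma::uword)(z + 1) * Xp * Yp + (arma::uword)(y + 1) * Xp + 1);
    }
}

// One output row (length n) of the 27-tap stencil in a single fused
// pass: rows9 holds the 9 padded source rows (one per (dy, dz) pair,
// starting at dx = 0); each contributes its 3 x-taps. w is ordered
// dx + 3*dy + 9*dz.
HOT_CLONES
static void stencil_row(double* __restrict dst, const double* const* rows9,
                        const double* __restrict w, int n) {
  const double* __restrict r0 = rows9[0]; const double* __restrict r1 = rows9[1];
  const double* __restrict r2 = rows9[2]; const double* __restrict r3 = rows9[3];
  const double* __restrict r4 = rows9[4]; const double* __restrict r5 = rows9[5];
  const double* __restrict r6 = rows9[6]; const double* __restrict r7 = rows9[7];
  const double* __restrict r8 = rows9[8];
  for (int i = 0; i < n; ++i) {
    double a = dst[i];
    a += w[0] * r0[i] + w[1] * r0[i + 1] + w[2] * r0[i + 2];
    a += w[3] * r1[i] + w[4] * r1[i + 1] + w[5] * r1[i + 2];
    a += w[6] * r2[i] + w[7] * r2[i + 1] + w[8] * r2[i + 2];
    a += w[9] * r3[i] + w[10] * r3[i + 1] + w[11] * r3[i + 2];
    a += w[12] * r4[i] + w[13] * r4[i + 1] + w[14] * r4[i + 2];
    a += w[15] * r5[i] + w[16] * r5[i + 1] + w[17] * r5[i + 2];
    a += w[18] * r6[i] + w[19] * r6[i + 1] + w[20] * r6[i + 2];
    a += w[21] * r7[i] + w[22] * r7[i + 1] + w[23] * r7[i + 2];
    a += w[24] * r8[i] + w[25] * r8[i + 1] + w[26] * r8[i + 2];
    dst[i] = a;
  }
}

// Weight-gradient dots for one row: acc[3q + d] += sum_i g(i) * s_q(i + d),
// three taps per source row sharing the loads.
HOT_CLONES
static void stencil_row_dots(const double* __restrict g,
                             const double* const* rows9,
                             double* __restrict acc, int n) {
  for (int q = 0; q < 9; ++q) {
    const double* __restrict s = rows9[q];
    double a0 = 0.0, a1 = 0.0, a2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double gi = g[i];
      a0 += gi * s[i];
      a1 += gi * s[i + 1];
      a2 += gi * s[i + 2];
    }
    acc[3 * q] += a0; acc[3 * q + 1] += a1; acc[3 * q + 2] += a2;
  }
}

// im2col for the small-volume GEMM path (deep network levels, where the
// stencil's per-row overhead dominates): (27 * Cin) x V, row index
// r = dx + 3*dy + 9*dz + 27*ci, voxel-major so columns are contiguous.
static arma::mat im2col3(const double* x, int X, int Y, int Z, int Cin) {
  const arma::uword V = (arma::uword)X * Y * Z;
  const arma::uword R = 27 * (arma::uword)Cin;
  arma::mat cols(R, V);
  double* C = cols.memptr();
  arma::uword v = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx, ++v) {
        double* col = C + v * R;
        arma::uword r = 0;
        for (int c = 0; c < Cin; ++c) {
          const double* xc = x + (arma::uword)c * V;
          for (int dz = 0; dz < 3; ++dz) {
            const int sz = z + dz - 1;
            const bool okz = sz >= 0 && sz < Z;
            for (int dy = 0; dy < 3; ++dy) {
              const int sy = y + dy - 1;
              if (!okz || sy < 0 || sy >= Y) {
                col[r] = col[r + 1] = col[r + 2] = 0.0; r += 3;
              } else {
                const double* row = xc + vidx(0, sy, sz, X, Y);
                for (int dx = 0; dx < 3; ++dx, ++r) {
                  const int sx = xx + dx - 1;
                  col[r] = (sx >= 0 && sx < X) ? row[sx] : 0.0;
                }
              }
            }
          }
        }
      }
  return cols;
}

static void col2im3(const arma::mat& cols, double* dx_out, int X, int Y,
                    int Z, int Cin) {
  const arma::uword V = (arma::uword)X * Y * Z;
  const arma::uword R = 27 * (arma::uword)Cin;
  const double* C = cols.memptr();
  arma::uword v = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx, ++v) {
        const double* col = C + v * R;
        arma::uword r = 0;
        for (int c = 0; c < Cin; ++c) {
          double* xc = dx_out + (arma::uword)c * V;
          for (int dz = 0; dz < 3; ++dz) {
            const int sz = z + dz - 1;
            const bool okz = sz >= 0 && sz < Z;
            for (int dy = 0; dy < 3; ++dy) {
              const int sy = y + dy - 1;
              if (!okz || sy < 0 || sy >= Y) { r += 3; continue; }
              double* row = xc + vidx(0, sy, sz, X, Y);
              for (int dx = 0; dx < 3; ++dx, ++r) {
                const int sx = xx + dx - 1;
                if (sx >= 0 && sx < X) row[sx] += col[r];
              }
            }
          }
        }
      }
}

// below this voxel count the GEMM path beats the stencil
static const arma::uword GEMM_MAX_V = 4096;

// Direct "same" convolution: y(v, co) = b[co] +
//   sum_{ci, dz, dy, dx} W[dx + k*dy + k^2*dz + k^3*ci, co] *
//                        x(v + (dx-p, dy-p, dz-p), ci).
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims, int cin,
                             NumericMatrix wmat, NumericVector bias, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword V = (arma::uword)X * Y * Z;
  const int cout = wmat.ncol();
  NumericVector res(V * cout);
  const double* xp = x.begin();
  if (k == 1) {
    for (int co = 0; co < cout; ++co) {
      double* yc = res.begin() + (arma::uword)co * V;
      std::fill(yc, yc + V, bias[co]);
      for (int ci = 0; ci < cin; ++ci)
        shift_axpy(yc, xp + (arma::uword)ci * V, wmat(ci, co), 0, 0, 0, X, Y, Z);
    }
    res.attr("dim") = IntegerVector::create(X, Y, Z, cout);
    return res;
  }
  if (V <= GEMM_MAX_V) {
    arma::mat W((double*)wmat.begin(), wmat.nrow(), cout, false);
    arma::mat cols = im2col3(xp, X, Y, Z, cin);
    arma::mat out(res.begin(), V, cout, false, true);
    out = cols.t() * W;
    for (int co = 0; co < cout; ++co) out.col(co) += bias[co];
    res.attr("dim") = IntegerVector::create(X, Y, Z, cout);
    return res;
  }
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const arma::uword Vp = (arma::uword)Xp * Yp * Zp;
  std::vector<double> xpad((arma::uword)cin * Vp);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel(xp + (arma::uword)ci * V, xpad.data() + (arma::uword)ci * Vp,
                X, Y, Z);
  const double* rows[9];
  for (int co = 0; co < cout; ++co) {
    double* yc = res.begin() + (arma::uword)co * V;
    std::fill(yc, yc + V, bias[co]);
    for (int ci = 0; ci < cin; ++ci) {
      const double* wc = &wmat(27 * ci, co);
      const double* pc = xpad.data() + (arma::uword)ci * Vp;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y) {
          for (int q = 0; q < 9; ++q) {
            rows[q] = pc + (arma::uword)(z + q / 3) * Xp * Yp +
              (arma::uword)(y + q % 3) * Xp;
          }
          stencil_row(yc + vidx(0, y, z, X, Y), rows, wc, X);
        }
    }
  }
  res.attr("dim") = IntegerVector::create(X, Y, Z, cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, int cin,
                    NumericMatrix wmat, NumericVector gy, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword V = (arma::uword)X * Y * Z;
  const int cout = wmat.ncol();
  NumericMatrix dW(wmat.nrow(), cout);
  NumericVector db(cout);
  NumericVector dx(V * cin);
  std::fill(dx.begin(), dx.end(), 0.0);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  if (k == 1) {
    for (int co = 0; co < cout; ++co) {
      const double* gc = gp + (arma::uword)co * V;
      double s = 0.0;
      for (arma::uword i = 0; i < V; ++i) s += gc[i];
      db[co] = s;
      for (int ci = 0; ci < cin; ++ci) {
        dW(ci, co) = shift_dot(gc, xp + (arma::uword)ci * V, 0, 0, 0, X, Y, Z);
        shift_axpy(dx.begin() + (arma::uword)ci * V, gc, wmat(ci, co),
                   0, 0, 0, X, Y, Z);
      }
    }
    dx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  if (V <= GEMM_MAX_V) {
    arma::mat W((double*)wmat.begin(), wmat.nrow(), cout, false);
    arma::mat Gy((double*)gp, V, cout, false);
    arma::mat cols = im2col3(xp, X, Y, Z, cin);
    arma::mat dWm(dW.begin(), wmat.nrow(), cout, false, true);
    dWm = cols * Gy;
    for (int co = 0; co < cout; ++co) db[co] = arma::accu(Gy.col(co));
    arma::mat dcols = W * Gy.t();
    col2im3(dcols, dx.begin(), X, Y, Z, cin);
    dx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  const int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  const arma::uword Vp = (arma::uword)Xp * Yp * Zp;
  // pad x (for dW) and gy (for dx)
  std::vector<double> xpad((arma::uword)cin * Vp);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel(xp + (arma::uword)ci * V, xpad.data() + (arma::uword)ci * Vp,
                X, Y, Z);
  std::vector<double> gpad(Vp);
  const double* rows[9];
  double wrev[27], acc[27];
  for (int co = 0; co < cout; ++co) {
    const double* gc = gp + (arma::uword)co * V;
    double s = 0.0;
    for (arma::uword i = 0; i < V; ++i) s += gc[i];
    db[co] = s;
    pad_channel(gc, gpad.data(), X, Y, Z);
    for (int ci = 0; ci < cin; ++ci) {
      const double* wc = &wmat(27 * ci, co);
      double* dwc = &dW(27 * ci, co);
      double* dxc = dx.begin() + (arma::uword)ci * V;
      const double* pc = xpad.data() + (arma::uword)ci * Vp;
      // dx(v) += sum_t W[26 - t] gy(v + o_t): same stencil, taps reversed
      for (int t = 0; t < 27; ++t) wrev[t] = wc[26 - t];
      std::fill(acc, acc + 27, 0.0);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y) {
          for (int q = 0; q < 9; ++q) {
            rows[q] = gpad.data() + (arma::uword)(z + q / 3) * Xp * Yp +
              (arma::uword)(y + q % 3) * Xp;
          }
          stencil_row(dxc + vidx(0, y, z, X, Y), rows, wrev, X);
          // dW[t] += sum_x gy(row) * x(row shifted by tap t)
          for (int q = 0; q < 9; ++q) {
            rows[q] = pc + (arma::uword)(z + q / 3) * Xp * Yp +
              (arma::uword)(y + q % 3) * Xp;
          }
          stencil_row_dots(gc + vidx(0, y, z, X, Y), rows, acc, X);
        }
      for (int t = 0; t < 27; ++t) dwc[t] = acc[t];
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Fused instance normalisation + leaky ReLU, per channel over the
// spatial voxels: y = lrelu(g * (x - mu) / sqrt(var + eps) + b).
// [[Rcpp::export]]
List cpp_in_lrelu_fwd(NumericVector x, IntegerVector dims, int C,
                      NumericVector g, NumericVector b, double slope,
                      double eps) {
  const arma::uword V = (arma::uword)dims[0] * dims[1] * dims[2];
  NumericVector y(V * C), mu(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (arma::uword)c * V;
    double* yc = y.begin() + (arma::uword)c * V;
    double s = 0.0, s2 = 0.0;
    for (arma::uword i = 0; i < V; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / V;
    const double var = s2 / V - m * m;
    const double isd = 1.0 / std::sqrt(var + eps);
    mu[c] = m; inv_sd[c] = isd;
    const double gc = g[c], bc = b[c];
    for (arma::uword i = 0; i < V; ++i) {
      const double z = gc * (xc[i] - m) * isd + bc;
      yc[i] = z > 0 ? z : slope * z;
    }
  }
  y.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], C);
  return List::create(_["y"] = y, _["mu"] = mu, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List cpp_in_lrelu_bwd(NumericVector x, IntegerVector dims, int C,
                      NumericVector g, NumericVector b, double slope,
                      NumericVector mu, NumericVector inv_sd,
                      NumericVector gy) {
  const arma::uword V = (arma::uword)dims[0] * dims[1] * dims[2];
  NumericVector dx(V * C), dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (arma::uword)c * V;
    const double* gc_ = gy.begin() + (arma::uword)c * V;
    double* dxc = dx.begin() + (arma::uword)c * V;
    const double m = mu[c], isd = inv_sd[c], gg = g[c], bb = b[c];
    double sdz = 0.0, sdzx = 0.0, sdg = 0.0;
    for (arma::uword i = 0; i < V; ++i) {
      const double xh = (xc[i] - m) * isd;
      const double z = gg * xh + bb;
      const double dz = gc_[i] * (z > 0 ? 1.0 : slope);
      sdz += dz;
      sdg += dz * xh;
      sdzx += dz * gg * xh; // for mean(dxhat * xhat)
      dxc[i] = dz * gg;     // dxhat, finished below
    }
    dg[c] = sdg; db[c] = sdz;
    const double m1 = (sdz * gg) / V;     // mean(dxhat)
    const double m2 = sdzx / V;           // mean(dxhat * xhat)
    for (arma::uword i = 0; i < V; ++i) {
      const double xh = (xc[i] - m) * isd;
      dxc[i] = isd * (dxc[i] - m1 - xh * m2);
    }
  }
  dx.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], C);
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// 2x2x2 max pooling, stride 2. Dims must be even.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims, int C) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const arma::uword Vi = (arma::uword)X * Y * Z, Vo = (arma::uword)Xo * Yo * Zo;
  NumericVector y(Vo * C);
  IntegerVector idx(Vo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (arma::uword)c * Vi;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double best = -1e300; arma::uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                arma::uword ii = vidx(2 * xx + dx, 2 * yy + dy, 2 * z + dz, X, Y);
                if (xc[ii] > best) { best = xc[ii]; bi = ii; }
              }
          arma::uword oo = vidx(xx, yy, z, Xo, Yo) + (arma::uword)c * Vo;
          y[oo] = best;
          idx[oo] = (int)(bi + (arma::uword)c * Vi);
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector in_dims, int C) {
  const arma::uword Vi = (arma::uword)in_dims[0] * in_dims[1] * in_dims[2];
  NumericVector dx(Vi * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  for (R_xlen_t i = 0; i < gy.size(); ++i) dx[idx[i]] += gy[i];
  dx.attr("dim") = IntegerVector::create(in_dims[0], in_dims[1], in_dims[2], C);
  return dx;
}

// Trilinear 2x upsampling; source coordinate s = (o + 0.5)/2 - 0.5, clamped.
static inline void lin_w(int o, int n_in, int& i0, int& i1, double& w1) {
  double s = (o + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector dims, int C) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const arma::uword Vi = (arma::uword)X * Y * Z, Vo = (arma::uword)Xo * Yo * Zo;
  NumericVector y(Vo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (arma::uword)c * Vi;
    double* yc = y.begin() + (arma::uword)c * Vo;
    for (int z = 0; z < Zo; ++z) {
      int z0, z1; double wz; lin_w(z, Z, z0, z1, wz);
      for (int yy = 0; yy < Yo; ++yy) {
        int y0, y1; double wy; lin_w(yy, Y, y0, y1, wy);
        for (int xx = 0; xx < Xo; ++xx) {
          int x0, x1; double wx; lin_w(xx, X, x0, x1, wx);
          double v =
            (1 - wz) * ((1 - wy) * ((1 - wx) * xc[vidx(x0, y0, z0, X, Y)] + wx * xc[vidx(x1, y0, z0, X, Y)]) +
                        wy * ((1 - wx) * xc[vidx(x0, y1, z0, X, Y)] + wx * xc[vidx(x1, y1, z0, X, Y)])) +
            wz * ((1 - wy) * ((1 - wx) * xc[vidx(x0, y0, z1, X, Y)] + wx * xc[vidx(x1, y0, z1, X, Y)]) +
                  wy * ((1 - wx) * xc[vidx(x0, y1, z1, X, Y)] + wx * xc[vidx(x1, y1, z1, X, Y)]));
          yc[vidx(xx, yy, z, Xo, Yo)] = v;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector in_dims, int C) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const arma::uword Vi = (arma::uword)X * Y * Z, Vo = (arma::uword)Xo * Yo * Zo;
  NumericVector dx(Vi * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (arma::uword)c * Vo;
    double* dc = dx.begin() + (arma::uword)c * Vi;
    for (int z = 0; z < Zo; ++z) {
      int z0, z1; double wz; lin_w(z, Z, z0, z1, wz);
      for (int yy = 0; yy < Yo; ++yy) {
        int y0, y1; double wy; lin_w(yy, Y, y0, y1, wy);
        for (int xx = 0; xx < Xo; ++xx) {
          int x0, x1; double wx; lin_w(xx, X, x0, x1, wx);
          const double g = gc[vidx(xx, yy, z, Xo, Yo)];
          dc[vidx(x0, y0, z0, X, Y)] += (1 - wz) * (1 - wy) * (1 - wx) * g;
          dc[vidx(x1, y0, z0, X, Y)] += (1 - wz) * (1 - wy) * wx * g;
          dc[vidx(x0, y1, z0, X, Y)] += (1 - wz) * wy * (1 - wx) * g;
          dc[vidx(x1, y1, z0, X, Y)] += (1 - wz) * wy * wx * g;
          dc[vidx(x0, y0, z1, X, Y)] += wz * (1 - wy) * (1 - wx) * g;
          dc[vidx(x1, y0, z1, X, Y)] += wz * (1 - wy) * wx * g;
          dc[vidx(x0, y1, z1, X, Y)] += wz * wy * (1 - wx) * g;
          dc[vidx(x1, y1, z1, X, Y)] += wz * wy * wx * g;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return dx;
}

static inline double sample_tri(const double* v, int X, int Y, int Z,
                                double sx, double sy, double sz) {
  sx = std::min(std::max(sx, 0.0), (double)X - 1);
  sy = std::min(std::max(sy, 0.0), (double)Y - 1);
  sz = std::min(std::max(sz, 0.0), (double)Z - 1);
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
  double wx = sx - x0, wy = sy - y0, wz = sz - z0;
  return (1 - wz) * ((1 - wy) * ((1 - wx) * v[vidx(x0, y0, z0, X, Y)] + wx * v[vidx(x1, y0, z0, X, Y)]) +
                     wy * ((1 - wx) * v[vidx(x0, y1, z0, X, Y)] + wx * v[vidx(x1, y1, z0, X, Y)])) +
         wz * ((1 - wy) * ((1 - wx) * v[vidx(x0, y0, z1, X, Y)] + wx * v[vidx(x1, y0, z1, X, Y)]) +
               wy * ((1 - wx) * v[vidx(x0, y1, z1, X, Y)] + wx * v[vidx(x1, y1, z1, X, Y)]));
}

static inline double sample_nn(const double* v, int X, int Y, int Z,
                               double sx, double sy, double sz) {
  int x = (int)std::lround(sx), y = (int)std::lround(sy), z = (int)std::lround(sz);
  x = std::min(std::max(x, 0), X - 1);
  y = std::min(std::max(y, 0), Y - 1);
  z = std::min(std::max(z, 0), Z - 1);
  return v[vidx(x, y, z, X, Y)];
}

// Resample a 3D volume to a new grid. The centre of the first voxel is
// the common physical anchor (ITK convention): s_in = i * sp_out / sp_in.
// Integer spacing ratios therefore round-trip exactly under nearest
// interpolation.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericVector sp_in, IntegerVector out_dims,
                           NumericVector sp_out, bool nearest) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = out_dims[0], Yo = out_dims[1], Zo = out_dims[2];
  NumericVector out((arma::uword)Xo * Yo * Zo);
  const double* v = vol.begin();
  arma::uword o = 0;
  for (int z = 0; z < Zo; ++z) {
    double sz = z * sp_out[2] / sp_in[2];
    for (int y = 0; y < Yo; ++y) {
      double sy = y * sp_out[1] / sp_in[1];
      for (int x = 0; x < Xo; ++x, ++o) {
        double sx = x * sp_out[0] / sp_in[0];
        out[o] = nearest ? sample_nn(v, X, Y, Z, sx, sy, sz)
                         : sample_tri(v, X, Y, Z, sx, sy, sz);
      }
    }
  }
  out.attr("dim") = out_dims;
  return out;
}

// Affine resampling on the same grid (voxel units):
// source = M %*% (o - centre) + centre + shift.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dims,
                                NumericMatrix M, NumericVector centre,
                                NumericVector shift, bool nearest) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out((arma::uword)X * Y * Z);
  const double* v = vol.begin();
  arma::uword o = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++o) {
        double dx = x - centre[0], dy = y - centre[1], dz = z - centre[2];
        double sx = M(0, 0) * dx + M(0, 1) * dy + M(0, 2) * dz + centre[0] + shift[0];
        double sy = M(1, 0) * dx + M(1, 1) * dy + M(1, 2) * dz + centre[1] + shift[1];
        double sz = M(2, 0) * dx + M(2, 1) * dy + M(2, 2) * dz + centre[2] + shift[2];
        out[o] = nearest ? sample_nn(v, X, Y, Z, sx, sy, sz)
                         : sample_tri(v, X, Y, Z, sx, sy, sz);
      }
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a binary mask, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(NumericVector mask, IntegerVector dims, int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword V = (arma::uword)X * Y * Z;
  IntegerVector lab(V);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<arma::uword> stack;
  for (arma::uword s = 0; s < V; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      arma::uword cur = stack.back(); stack.pop_back();
      int x = cur % X, y = (cur / X) % Y, z = cur / ((arma::uword)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
            arma::uword ni = vidx(nx, ny, nz, X, Y);
            if (mask[ni] != 0 && lab[ni] == 0) { lab[ni] = next; stack.push_back(ni); }
          }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Fill background holes: background components (6-connectivity) not touching
// the volume border become foreground.
// [[Rcpp::export]]
NumericVector cpp_fill_holes(NumericVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const arma::uword V = (arma::uword)X * Y * Z;
  std::vector<char> outside(V, 0);
  std::vector<arma::uword> stack;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        if (x != 0 && x != X - 1 && y != 0 && y != Y - 1 && z != 0 && z != Z - 1) continue;
        arma::uword i = vidx(x, y, z, X, Y);
        if (mask[i] == 0 && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    arma::uword cur = stack.back(); stack.pop_back();
    int x = cur % X, y = (cur / X) % Y, z = cur / ((arma::uword)X * Y);
    for (int n = 0; n < 6; ++n) {
      int nx = x + dxs[n], ny = y + dys[n], nz = z + dzs[n];
      if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
      arma::uword ni = vidx(nx, ny, nz, X, Y);
      if (mask[ni] == 0 && !outside[ni]) { outside[ni] = 1; stack.push_back(ni); }
    }
  }
  NumericVector out(V);
  for (arma::uword i = 0; i < V; ++i) out[i] = (mask[i] != 0 || !outside[i]) ? 1.0 : 0.0;
  out.attr("dim") = dims;
  return out;
}
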