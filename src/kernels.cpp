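// Numeric kernels for the 3D UNet localizer and volumetric morphology.
// Convolutions use im2col over z-slabs (bounded scratch memory) feeding
// BLAS matrix products; backward passes rebuild the same patch matrices.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int i, int j, int k, int c,
                            int d1, int d2, int d3) {
  return (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * (k + (R_xlen_t)d3 * c));
}

static const int SLAB = 16;

// gather 3x3x3 patches (zero padded) for output z in [z0, z1) into
// Kt (ncol x 27*cin); column r = kx+3*ky+9*kz+27*c matches the column-major
// flattening of a (3,3,3,cin) weight block.
// single precision: the convolutions are memory-bandwidth bound and float
// halves the traffic; weight updates re-accumulate in double on the R side.
static void im2col_slab(const double* x, int d1, int d2, int d3, int cin,
                        int z0, int z1, arma::fmat& Kt) {
  const int plane = d1 * d2;
  Kt.zeros();
  for (int c = 0; c < cin; ++c)
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          int r = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
          float* dst0 = Kt.colptr(r);
          for (int z = z0; z < z1; ++z) {
            int zz = z + kz;
            if (zz < 0 || zz >= d3) continue;
            for (int j = 0; j < d2; ++j) {
              int jj = j + ky;
              if (jj < 0 || jj >= d2) continue;
              int i_lo = std::max(0, -kx), i_hi = std::min(d1, d1 - kx);
              if (i_lo >= i_hi) continue;
              const double* src = x + idx4(i_lo + kx, jj, zz, c, d1, d2, d3);
              float* dst = dst0 + (R_xlen_t)(z - z0) * plane + (R_xlen_t)j * d1 + i_lo;
              for (int i = 0; i < i_hi - i_lo; ++i) dst[i] = (float)src[i];
            }
          }
        }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector b) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  int cout = Wm.ncol();
  if (Wm.nrow() != 27 * cin) stop("weight/input channel mismatch");
  const int plane = d1 * d2;
  arma::fmat W = arma::conv_to<arma::fmat>::from(
      arma::mat(Wm.begin(), Wm.nrow(), cout, false));
  NumericVector out((R_xlen_t)plane * d3 * cout);
  arma::fmat Kt((R_xlen_t)plane * std::min(SLAB, d3), 27 * cin);
  for (int z0 = 0; z0 < d3; z0 += SLAB) {
    int z1 = std::min(z0 + SLAB, d3);
    R_xlen_t ncol = (R_xlen_t)plane * (z1 - z0);
    if ((R_xlen_t)Kt.n_rows != ncol) Kt.set_size(ncol, 27 * cin);
    im2col_slab(x.begin(), d1, d2, d3, cin, z0, z1, Kt);
    arma::fmat Y = Kt * W;  // ncol x cout
    for (int co = 0; co < cout; ++co) {
      double bb = b[co];
      double* o = out.begin() + idx4(0, 0, z0, co, d1, d2, d3);
      const float* y = Y.colptr(co);
      for (R_xlen_t t = 0; t < ncol; ++t) o[t] = (double)y[t] + bb;
    }
  }
  out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims,
                   NumericMatrix Wm, NumericVector dy) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  int cout = Wm.ncol();
  const int plane = d1 * d2;
  arma::fmat W = arma::conv_to<arma::fmat>::from(
      arma::mat(Wm.begin(), Wm.nrow(), cout, false));
  NumericVector dx((R_xlen_t)plane * d3 * cin);
  arma::fmat dW(27 * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::fmat Kt((R_xlen_t)plane * std::min(SLAB, d3), 27 * cin);
  for (int z0 = 0; z0 < d3; z0 += SLAB) {
    int z1 = std::min(z0 + SLAB, d3);
    R_xlen_t ncol = (R_xlen_t)plane * (z1 - z0);
    if ((R_xlen_t)Kt.n_rows != ncol) Kt.set_size(ncol, 27 * cin);
    im2col_slab(x.begin(), d1, d2, d3, cin, z0, z1, Kt);
    arma::fmat dY(ncol, cout);
    for (int co = 0; co < cout; ++co) {
      const double* g = dy.begin() + idx4(0, 0, z0, co, d1, d2, d3);
      float* dc = dY.colptr(co);
      double acc = 0;
      for (R_xlen_t t = 0; t < ncol; ++t) { dc[t] = (float)g[t]; acc += g[t]; }
      db[co] += acc;
    }
    dW += Kt.t() * dY;
    arma::fmat dKt = dY * W.t();  // ncol x 27*cin
    // col2im: scatter-add patches back into dx
    for (int c = 0; c < cin; ++c)
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            int r = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * c;
            const float* src0 = dKt.colptr(r);
            for (int z = z0; z < z1; ++z) {
              int zz = z + kz;
              if (zz < 0 || zz >= d3) continue;
              for (int j = 0; j < d2; ++j) {
                int jj = j + ky;
                if (jj < 0 || jj >= d2) continue;
                int i_lo = std::max(0, -kx), i_hi = std::min(d1, d1 - kx);
                if (i_lo >= i_hi) continue;
                double* dst = dx.begin() + idx4(i_lo + kx, jj, zz, c, d1, d2, d3);
                const float* src = src0 + (R_xlen_t)(z - z0) * plane +
                                    (R_xlen_t)j * d1 + i_lo;
                for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += (double)src[i];
              }
            }
          }
  }
  arma::mat dWd = arma::conv_to<arma::mat>::from(dW);
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dWd),
                      _["db"] = wrap(db));
}

// 2x2x2 pooling, stride 2. mode: 0 = average, 1 = max (records argmax).
// [[Rcpp::export]]
List cpp_pool_fw(NumericVector x, IntegerVector dims, int mode) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector y((R_xlen_t)o1 * o2 * o3 * C);
  IntegerVector arg(mode == 1 ? (R_xlen_t)o1 * o2 * o3 * C : 0);
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++t) {
          double acc = mode == 1 ? -1e300 : 0.0;
          R_xlen_t best = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                R_xlen_t s = idx4(2 * i + dxx, 2 * j + dyy, 2 * k + dz, c,
                                  d1, d2, d3);
                double v = x[s];
                if (mode == 1) { if (v > acc) { acc = v; best = s; } }
                else acc += v;
              }
          if (mode == 1) { y[t] = acc; arg[t] = (int)best; }
          else y[t] = acc / 8.0;
        }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bw(NumericVector dy, IntegerVector dims_in, int mode,
                          IntegerVector arg) {
  int d1 = dims_in[0], d2 = dims_in[1], d3 = dims_in[2], C = dims_in[3];
  int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector dx((R_xlen_t)d1 * d2 * d3 * C);
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++t) {
          double g = dy[t];
          if (mode == 1) {
            dx[arg[t]] += g;
          } else {
            double g8 = g / 8.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dyy = 0; dyy < 2; ++dyy)
                for (int dxx = 0; dxx < 2; ++dxx)
                  dx[idx4(2 * i + dxx, 2 * j + dyy, 2 * k + dz, c,
                          d1, d2, d3)] += g8;
          }
        }
  dx.attr("dim") = dims_in;
  return dx;
}

// trilinear 2x upsampling (align_corners = false convention)
static void up_weights(int dout, int din, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& w) {
  i0.resize(dout); i1.resize(dout); w.resize(dout);
  for (int o = 0; o < dout; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(s);
    double wt = s - lo;
    if (lo < 0) { lo = 0; wt = 0.0; }
    if (lo >= din - 1) { lo = din - 1; wt = 0.0; }
    i0[o] = lo; i1[o] = std::min(lo + 1, din - 1); w[o] = wt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  up_weights(o1, d1, a0, a1, wa);
  up_weights(o2, d2, b0, b1, wb);
  up_weights(o3, d3, c0, c1, wc);
  NumericVector y((R_xlen_t)o1 * o2 * o3 * C);
  R_xlen_t t = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++t) {
          double v = 0.0;
          for (int cz = 0; cz < 2; ++cz) {
            double wz = cz ? wc[k] : 1 - wc[k];
            if (wz == 0) continue;
            int z = cz ? c1[k] : c0[k];
            for (int cy = 0; cy < 2; ++cy) {
              double wy = cy ? wb[j] : 1 - wb[j];
              if (wy == 0) continue;
              int yy = cy ? b1[j] : b0[j];
              for (int cx = 0; cx < 2; ++cx) {
                double wx = cx ? wa[i] : 1 - wa[i];
                if (wx == 0) continue;
                int xx = cx ? a1[i] : a0[i];
                v += wz * wy * wx * x[idx4(xx, yy, z, ch, d1, d2, d3)];
              }
            }
          }
          y[t] = v;
        }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector dy, IntegerVector dims_in) {
  int d1 = dims_in[0], d2 = dims_in[1], d3 = dims_in[2], C = dims_in[3];
  int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  up_weights(o1, d1, a0, a1, wa);
  up_weights(o2, d2, b0, b1, wb);
  up_weights(o3, d3, c0, c1, wc);
  NumericVector dx((R_xlen_t)d1 * d2 * d3 * C);
  R_xlen_t t = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++t) {
          double g = dy[t];
          if (g == 0) continue;
          for (int cz = 0; cz < 2; ++cz) {
            double wz = cz ? wc[k] : 1 - wc[k];
            if (wz == 0) continue;
            int z = cz ? c1[k] : c0[k];
            for (int cy = 0; cy < 2; ++cy) {
              double wy = cy ? wb[j] : 1 - wb[j];
              if (wy == 0) continue;
              int yy = cy ? b1[j] : b0[j];
              for (int cx = 0; cx < 2; ++cx) {
                double wx = cx ? wa[i] : 1 - wa[i];
                if (wx == 0) continue;
                int xx = cx ? a1[i] : a0[i];
                dx[idx4(xx, yy, z, ch, d1, d2, d3)] += wz * wy * wx * g;
              }
            }
          }
        }
  dx.attr("dim") = dims_in;
  return dx;
}

// 6-connected component labelling of a 3D logical array (BFS).
// Labels are 1..n in first-encounter (column-major scan) order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % d1);
      int j = (int)((v / d1) % d2);
      int k = (int)(v / plane);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t u = ii + (R_xlen_t)d1 * jj + plane * kk;
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// fused instance-norm forward: per-channel normalization over all voxels
// [[Rcpp::export]]
List cpp_instnorm_fw(NumericVector z, IntegerVector dims, double eps) {
  int C = dims[3];
  R_xlen_t N = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector y(N * C);
  NumericVector s(C);
  for (int c = 0; c < C; ++c) {
    const double* zc = z.begin() + N * c;
    double mu = 0, m2 = 0;
    for (R_xlen_t i = 0; i < N; ++i) mu += zc[i];
    mu /= N;
    for (R_xlen_t i = 0; i < N; ++i) { double d = zc[i] - mu; m2 += d * d; }
    double sd = std::sqrt(m2 / N + eps);
    double* yc = y.begin() + N * c;
    for (R_xlen_t i = 0; i < N; ++i) yc[i] = (zc[i] - mu) / sd;
    s[c] = sd;
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector cpp_instnorm_bw(NumericVector dy, NumericVector y,
                              IntegerVector dims, NumericVector s) {
  int C = dims[3];
  R_xlen_t N = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector dz(N * C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + N * c;
    const double* yc = y.begin() + N * c;
    double c1 = 0, c2 = 0;
    for (R_xlen_t i = 0; i < N; ++i) { c1 += dyc[i]; c2 += dyc[i] * yc[i]; }
    c1 /= N; c2 /= N;
    double* dzc = dz.begin() + N * c;
    double inv = 1.0 / s[c];
    for (R_xlen_t i = 0; i < N; ++i)
      dzc[i] = (dyc[i] - c1 - yc[i] * c2) * inv;
  }
  dz.attr("dim") = dims;
  return dz;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fw(NumericVector y, double slope) {
  NumericVector a(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i)
    a[i] = y[i] > 0 ? y[i] : slope * y[i];
  a.attr("dim") = y.attr("dim");
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bw(NumericVector da, NumericVector y, double slope) {
  NumericVector dy(da.size());
  for (R_xlen_t i = 0; i < da.size(); ++i)
    dy[i] = y[i] > 0 ? da[i] : slope * da[i];
  dy.attr("dim") = da.attr("dim");
  return dy;
}
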