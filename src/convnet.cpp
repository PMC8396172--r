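#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3-D convolution kernels for the volumetric network. Tensors are R arrays
// in column-major order with dims (x, y, z, channels, batch); weights are
// (kx, ky, kz, c_in, c_out). Zero padding, cubic kernels, isotropic stride.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  int k = wd[0], co = wd[4];
  int ox = out_size(nx, k, stride, pad), oy = out_size(ny, k, stride, pad),
      oz = out_size(nz, k, stride, pad);
  NumericVector y((R_xlen_t)ox * oy * oz * co * nb);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co, nb);
  const double* X = x.begin();
  const double* W = w.begin();
  double* Y = y.begin();
  R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = xsz * nz, xsn = xsc * ci;
  R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = ysz * oz, ysn = ysc * co;
  R_xlen_t wsy = k, wsz = (R_xlen_t)k * k, wsc = wsz * k, wso = wsc * ci;
  std::vector<int> lo_x(ox), hi_x(ox), lo_y(oy), hi_y(oy), lo_z(oz), hi_z(oz);
  for (int i = 0; i < ox; i++) {
    lo_x[i] = std::max(0, pad - i * stride);
    hi_x[i] = std::min(k - 1, nx - 1 - i * stride + pad);
  }
  for (int i = 0; i < oy; i++) {
    lo_y[i] = std::max(0, pad - i * stride);
    hi_y[i] = std::min(k - 1, ny - 1 - i * stride + pad);
  }
  for (int i = 0; i < oz; i++) {
    lo_z[i] = std::max(0, pad - i * stride);
    hi_z[i] = std::min(k - 1, nz - 1 - i * stride + pad);
  }
  for (int n = 0; n < nb; n++)
    for (int c = 0; c < co; c++) {
      double bias = b[c];
      for (int z = 0; z < oz; z++)
        for (int yy = 0; yy < oy; yy++)
          for (int xx = 0; xx < ox; xx++) {
            double acc = bias;
            int ib_x = xx * stride - pad, ib_y = yy * stride - pad,
                ib_z = z * stride - pad;
            for (int q = 0; q < ci; q++) {
              const double* Xq = X + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
              const double* Wq = W + (R_xlen_t)c * wso + (R_xlen_t)q * wsc;
              for (int kz = lo_z[z]; kz <= hi_z[z]; kz++)
                for (int ky = lo_y[yy]; ky <= hi_y[yy]; ky++) {
                  const double* Xrow = Xq + (ib_x) +
                    (R_xlen_t)(ib_y + ky) * xsy + (R_xlen_t)(ib_z + kz) * xsz;
                  const double* Wrow = Wq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  for (int kx = lo_x[xx]; kx <= hi_x[xx]; kx++)
                    acc += Xrow[kx] * Wrow[kx];
                }
            }
            Y[(R_xlen_t)n * ysn + (R_xlen_t)c * ysc + (R_xlen_t)z * ysz +
              (R_xlen_t)yy * ysy + xx] = acc;
          }
    }
  return y;
}

// Gradient w.r.t. the input: scatter dy through the weights.
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_data(NumericVector dy, NumericVector w,
                                  int stride, int pad, IntegerVector in_dim) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  int ox = yd[0], oy = yd[1], oz = yd[2], co = yd[3], nb = yd[4];
  int k = wd[0], ci = wd[3];
  int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  NumericVector dx((R_xlen_t)nx * ny * nz * ci * nb);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, ci, nb);
  const double* DY = dy.begin();
  const double* W = w.begin();
  double* DX = dx.begin();
  R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = xsz * nz, xsn = xsc * ci;
  R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = ysz * oz, ysn = ysc * co;
  R_xlen_t wsy = k, wsz = (R_xlen_t)k * k, wsc = wsz * k, wso = wsc * ci;
  for (int n = 0; n < nb; n++)
    for (int c = 0; c < co; c++)
      for (int z = 0; z < oz; z++)
        for (int yy = 0; yy < oy; yy++)
          for (int xx = 0; xx < ox; xx++) {
            double g = DY[(R_xlen_t)n * ysn + (R_xlen_t)c * ysc +
                          (R_xlen_t)z * ysz + (R_xlen_t)yy * ysy + xx];
            if (g == 0) continue;
            int ib_x = xx * stride - pad, ib_y = yy * stride - pad,
                ib_z = z * stride - pad;
            int lx = std::max(0, -ib_x), hx = std::min(k - 1, nx - 1 - ib_x);
            int ly = std::max(0, -ib_y), hy = std::min(k - 1, ny - 1 - ib_y);
            int lz = std::max(0, -ib_z), hz = std::min(k - 1, nz - 1 - ib_z);
            for (int q = 0; q < ci; q++) {
              double* Xq = DX + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
              const double* Wq = W + (R_xlen_t)c * wso + (R_xlen_t)q * wsc;
              for (int kz = lz; kz <= hz; kz++)
                for (int ky = ly; ky <= hy; ky++) {
                  double* Xrow = Xq + ib_x + (R_xlen_t)(ib_y + ky) * xsy +
                    (R_xlen_t)(ib_z + kz) * xsz;
                  const double* Wrow = Wq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  for (int kx = lx; kx <= hx; kx++)
                    Xrow[kx] += g * Wrow[kx];
                }
            }
          }
  return dx;
}

// Gradients w.r.t. weights and bias; returns list(dw, db).
// [[Rcpp::export]]
List cpp_conv3d_bwd_w(NumericVector x, NumericVector dy, int k, int stride,
                      int pad) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  int ox = yd[0], oy = yd[1], oz = yd[2], co = yd[3];
  NumericVector dw((R_xlen_t)k * k * k * ci * co);
  dw.attr("dim") = IntegerVector::create(k, k, k, ci, co);
  NumericVector db(co);
  const double* X = x.begin();
  const double* DY = dy.begin();
  double* DW = dw.begin();
  R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = xsz * nz, xsn = xsc * ci;
  R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = ysz * oz, ysn = ysc * co;
  R_xlen_t wsy = k, wsz = (R_xlen_t)k * k, wsc = wsz * k, wso = wsc * ci;
  for (int n = 0; n < nb; n++)
    for (int c = 0; c < co; c++) {
      double bacc = 0;
      for (int z = 0; z < oz; z++)
        for (int yy = 0; yy < oy; yy++)
          for (int xx = 0; xx < ox; xx++) {
            double g = DY[(R_xlen_t)n * ysn + (R_xlen_t)c * ysc +
                          (R_xlen_t)z * ysz + (R_xlen_t)yy * ysy + xx];
            bacc += g;
            if (g == 0) continue;
            int ib_x = xx * stride - pad, ib_y = yy * stride - pad,
                ib_z = z * stride - pad;
            int lx = std::max(0, -ib_x), hx = std::min(k - 1, nx - 1 - ib_x);
            int ly = std::max(0, -ib_y), hy = std::min(k - 1, ny - 1 - ib_y);
            int lz = std::max(0, -ib_z), hz = std::min(k - 1, nz - 1 - ib_z);
            for (int q = 0; q < ci; q++) {
              const double* Xq = X + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
              double* Wq = DW + (R_xlen_t)c * wso + (R_xlen_t)q * wsc;
              for (int kz = lz; kz <= hz; kz++)
                for (int ky = ly; ky <= hy; ky++) {
                  const double* Xrow = Xq + ib_x + (R_xlen_t)(ib_y + ky) * xsy +
                    (R_xlen_t)(ib_z + kz) * xsz;
                  double* Wrow = Wq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  for (int kx = lx; kx <= hx; kx++)
                    Wrow[kx] += g * Xrow[kx];
                }
            }
          }
      db[c] += bacc;
    }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Transposed ("up") convolution, kernel k, stride s, no padding:
// y[i*s + k] += x[i] * w. Weights are (k, k, k, c_out, c_in).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  int k = wd[0], co = wd[3];
  int ox = (nx - 1) * stride + k, oy = (ny - 1) * stride + k,
      oz = (nz - 1) * stride + k;
  NumericVector y((R_xlen_t)ox * oy * oz * co * nb);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co, nb);
  const double* X = x.begin();
  const double* W = w.begin();
  double* Y = y.begin();
  R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = xsz * nz, xsn = xsc * ci;
  R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = ysz * oz, ysn = ysc * co;
  R_xlen_t wsy = k, wsz = (R_xlen_t)k * k, wsc = wsz * k, wsi = wsc * co;
  for (int n = 0; n < nb; n++) {
    for (int c = 0; c < co; c++) {
      double* Yc = Y + (R_xlen_t)n * ysn + (R_xlen_t)c * ysc;
      double bias = b[c];
      for (R_xlen_t i = 0; i < ysc; i++) Yc[i] = bias;
    }
    for (int q = 0; q < ci; q++) {
      const double* Xq = X + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
      for (int c = 0; c < co; c++) {
        double* Yc = Y + (R_xlen_t)n * ysn + (R_xlen_t)c * ysc;
        const double* Wq = W + (R_xlen_t)q * wsi + (R_xlen_t)c * wsc;
        for (int z = 0; z < nz; z++)
          for (int yy = 0; yy < ny; yy++)
            for (int xx = 0; xx < nx; xx++) {
              double v = Xq[xx + (R_xlen_t)yy * xsy + (R_xlen_t)z * xsz];
              if (v == 0) continue;
              for (int kz = 0; kz < k; kz++)
                for (int ky = 0; ky < k; ky++) {
                  double* Yrow = Yc + (xx * stride) +
                    (R_xlen_t)(yy * stride + ky) * ysy +
                    (R_xlen_t)(z * stride + kz) * ysz;
                  const double* Wrow = Wq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  for (int kx = 0; kx < k; kx++)
                    Yrow[kx] += v * Wrow[kx];
                }
            }
      }
    }
  }
  return y;
}

// Backward of the transposed convolution: returns list(dx, dw, db).
// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, NumericVector dy, NumericVector w,
                     int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  int k = wd[0], co = wd[3];
  int ox = yd[0], oy = yd[1], oz = yd[2];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(co);
  const double* X = x.begin();
  const double* DY = dy.begin();
  const double* W = w.begin();
  double* DX = dx.begin();
  double* DW = dw.begin();
  R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = xsz * nz, xsn = xsc * ci;
  R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = ysz * oz, ysn = ysc * co;
  R_xlen_t wsy = k, wsz = (R_xlen_t)k * k, wsc = wsz * k, wsi = wsc * co;
  for (int c = 0; c < co; c++) {
    double acc = 0;
    for (int n = 0; n < nb; n++) {
      const double* Yc = DY + (R_xlen_t)n * ysn + (R_xlen_t)c * ysc;
      for (R_xlen_t i = 0; i < ysc; i++) acc += Yc[i];
    }
    db[c] = acc;
  }
  for (int n = 0; n < nb; n++)
    for (int q = 0; q < ci; q++) {
      const double* Xq = X + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
      double* DXq = DX + (R_xlen_t)n * xsn + (R_xlen_t)q * xsc;
      for (int c = 0; c < co; c++) {
        const double* Yc = DY + (R_xlen_t)n * ysn + (R_xlen_t)c * ysc;
        const double* Wq = W + (R_xlen_t)q * wsi + (R_xlen_t)c * wsc;
        double* DWq = DW + (R_xlen_t)q * wsi + (R_xlen_t)c * wsc;
        for (int z = 0; z < nz; z++)
          for (int yy = 0; yy < ny; yy++)
            for (int xx = 0; xx < nx; xx++) {
              R_xlen_t xi = xx + (R_xlen_t)yy * xsy + (R_xlen_t)z * xsz;
              double xv = Xq[xi];
              double gacc = 0;
              for (int kz = 0; kz < k; kz++)
                for (int ky = 0; ky < k; ky++) {
                  const double* Yrow = Yc + (xx * stride) +
                    (R_xlen_t)(yy * stride + ky) * ysy +
                    (R_xlen_t)(z * stride + kz) * ysz;
                  const double* Wrow = Wq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  double* DWrow = DWq + (R_xlen_t)ky * wsy + (R_xlen_t)kz * wsz;
                  for (int kx = 0; kx < k; kx++) {
                    double g = Yrow[kx];
                    gacc += g * Wrow[kx];
                    DWrow[kx] += g * xv;
                  }
                }
              DXq[xi] += gacc;
            }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
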