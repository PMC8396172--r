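#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear sampling of `vol` at continuous 0-based voxel coordinate (x,y,z).
// Coordinates outside the grid return `fill`.
static inline double sample_trilinear(const double* vol, int nx, int ny, int nz,
                                      double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = vol + x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample/warp: output voxel (i,j,k) (0-based) samples input at
// A %*% c(i,j,k) + t (continuous 0-based input voxel coordinates).
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector vol, IntegerVector out_dim,
                              NumericMatrix A, NumericVector t, double fill) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double* v = vol.begin();
  double* o = out.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; k++) {
    for (int j = 0; j < oy; j++) {
      double xb = a01 * j + a02 * k + t[0];
      double yb = a11 * j + a12 * k + t[1];
      double zb = a21 * j + a22 * k + t[2];
      for (int i = 0; i < ox; i++, idx++) {
        o[idx] = sample_trilinear(v, nx, ny, nz,
                                  a00 * i + xb, a10 * i + yb, a20 * i + zb, fill);
      }
    }
  }
  return out;
}

// Separable Gaussian blur, sigma in voxels per axis, reflecting boundaries.
static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) { w[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += w[i + r]; }
  for (auto& x : w) x /= s;
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int pos = axis == 0 ? i : (axis == 1 ? j : k);
        R_xlen_t base = i * sx + (R_xlen_t)j * sy + (R_xlen_t)k * sz - (R_xlen_t)pos * stride;
        double acc = 0;
        for (int q = -r; q <= r; q++) {
          int p = pos + q;
          if (p < 0) p = -p;              // reflect
          if (p > n - 1) p = 2 * (n - 1) - p;
          if (p < 0) p = 0;
          acc += w[q + r] * src[base + (R_xlen_t)p * stride];
        }
        dst[i * sx + (R_xlen_t)j * sy + (R_xlen_t)k * sz] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  blur_axis(a, b, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(b, a, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(a, b, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = d;
  return out;
}
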