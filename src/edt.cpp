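#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1-D squared distance transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z;
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * (q - v[k]));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in voxel units) from every nonzero voxel of `mask` to
// the nearest zero voxel. Zero voxels get distance 0. A mask with no zero
// voxels returns +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  // large finite sentinel: infinities break the parabola intersection math
  const double INF = 1e20;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) g[i] = mask[i] ? INF : 0.0;
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)j * sy + (R_xlen_t)k * sz;
      for (int i = 0; i < nx; i++) f[i] = g[base + i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)k * sz;
      for (int j = 0; j < ny; j++) f[j] = g[base + (R_xlen_t)j * sy];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)j * sy] = d[j];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)j * sy;
      for (int k = 0; k < nz; k++) f[k] = g[base + (R_xlen_t)k * sz];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; k++) g[base + (R_xlen_t)k * sz] = d[k];
    }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dm;
  return out;
}
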