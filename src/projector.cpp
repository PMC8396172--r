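#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Circular cone-beam geometry. The volume is centered on the isocenter;
// voxel index i (0-based) lies at physical x = (i - (nx-1)/2) * vox_mm.
// At view angle beta the source sits at sod*(cos b, sin b, 0); the flat
// detector is perpendicular to the central ray at distance sdd from the
// source, with in-plane axis u = (-sin b, cos b, 0) and axial axis v = z.

// Ray-driven forward projection (Joseph-style: trilinear samples at half-voxel
// steps along each source->pixel ray, times the step length in mm).
// vol holds linear attenuation per mm; output is unitless line integrals.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, double vox_mm,
                                  NumericVector angles, double sod, double sdd,
                                  int nu, int nv, double du, double dv) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int nviews = angles.size();
  NumericVector out((R_xlen_t)nu * nv * nviews);
  out.attr("dim") = IntegerVector::create(nu, nv, nviews);
  const double* v = vol.begin();
  double* o = out.begin();
  // volume bounding box in mm (outer voxel faces)
  double hx = nx * vox_mm / 2.0, hy = ny * vox_mm / 2.0, hz = nz * vox_mm / 2.0;
  double step = vox_mm / 2.0;
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int a = 0; a < nviews; a++) {
    double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    double Sx = sod * cb, Sy = sod * sb, Sz = 0.0;
    // detector center and axes
    double Cx = Sx - sdd * cb, Cy = Sy - sdd * sb, Cz = 0.0;
    double ux = -sb, uy = cb;
    for (int iv = 0; iv < nv; iv++) {
      double w = (iv - (nv - 1) / 2.0) * dv;
      for (int iu = 0; iu < nu; iu++) {
        double u = (iu - (nu - 1) / 2.0) * du;
        double Px = Cx + u * ux, Py = Cy + u * uy, Pz = Cz + w;
        double dx = Px - Sx, dy = Py - Sy, dz = Pz - Sz;
        double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= len; dy /= len; dz /= len;
        // slab clipping against the volume box
        double t0 = 0.0, t1 = len, acc = 0.0;
        bool ok = true;
        double p[3] = {Sx, Sy, Sz}, q[3] = {dx, dy, dz}, h[3] = {hx, hy, hz};
        for (int ax = 0; ax < 3 && ok; ax++) {
          if (std::fabs(q[ax]) < 1e-12) {
            if (p[ax] < -h[ax] || p[ax] > h[ax]) ok = false;
          } else {
            double ta = (-h[ax] - p[ax]) / q[ax];
            double tb = (h[ax] - p[ax]) / q[ax];
            if (ta > tb) std::swap(ta, tb);
            t0 = std::max(t0, ta);
            t1 = std::min(t1, tb);
            if (t0 >= t1) ok = false;
          }
        }
        double val = 0.0;
        if (ok) {
          int nstep = (int)std::ceil((t1 - t0) / step);
          double ds = (t1 - t0) / nstep;
          for (int s = 0; s < nstep; s++) {
            double t = t0 + (s + 0.5) * ds;
            double X = (Sx + t * dx) / vox_mm + cx;
            double Y = (Sy + t * dy) / vox_mm + cy;
            double Z = (Sz + t * dz) / vox_mm + cz;
            if (X < 0 || Y < 0 || Z < 0 || X > nx - 1 || Y > ny - 1 || Z > nz - 1)
              continue;
            int x0 = (int)X, y0 = (int)Y, z0 = (int)Z;
            if (x0 == nx - 1) x0--;
            if (y0 == ny - 1) y0--;
            if (z0 == nz - 1) z0--;
            double fx = X - x0, fy = Y - y0, fz = Z - z0;
            const double* b = v + x0 + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
            double c00 = b[0] * (1 - fx) + b[1] * fx;
            double c10 = b[sy] * (1 - fx) + b[sy + 1] * fx;
            double c01 = b[sz] * (1 - fx) + b[sz + 1] * fx;
            double c11 = b[sz + sy] * (1 - fx) + b[sz + sy + 1] * fx;
            acc += ((c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                    (c01 * (1 - fy) + c11 * fy) * fz) * ds;
          }
          val = acc;
        }
        o[(R_xlen_t)iu + (R_xlen_t)iv * nu + (R_xlen_t)a * nu * nv] = val;
      }
    }
  }
  return out;
}

// FDK voxel-driven backprojection of row-filtered projections expressed on
// the virtual detector through the isocenter (coordinates u' = u*sod/sdd).
// proj dims: (nu, nv, nviews); du_v, dv_v are virtual-detector pitches.
// Output accumulates sum over views of (sod/L)^2 * q(u', v'); the caller
// multiplies by the angular step.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector proj, IntegerVector out_dim,
                                  double vox_mm, NumericVector angles,
                                  double sod, double du_v, double dv_v) {
  int nu = ((IntegerVector)proj.attr("dim"))[0];
  int nv = ((IntegerVector)proj.attr("dim"))[1];
  int nviews = angles.size();
  int nx = out_dim[0], ny = out_dim[1], nz = out_dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = out_dim;
  double* ov = out.begin();
  const double* pv = proj.begin();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  for (int a = 0; a < nviews; a++) {
    double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double* pa = pv + (R_xlen_t)a * nu * nv;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; k++) {
      double z = (k - cz) * vox_mm;
      for (int j = 0; j < ny; j++) {
        double y = (j - cy) * vox_mm;
        for (int i = 0; i < nx; i++, idx++) {
          double x = (i - cx) * vox_mm;
          double L = sod - x * cb - y * sb;
          if (L <= 1e-6) continue;
          double w2 = (sod / L) * (sod / L);
          double up = sod * (-x * sb + y * cb) / L;
          double vp = sod * z / L;
          double U = up / du_v + cu;
          double V = vp / dv_v + cv;
          if (U < 0 || V < 0 || U > nu - 1 || V > nv - 1) continue;
          int u0 = (int)U, v0 = (int)V;
          if (u0 == nu - 1) u0--;
          if (v0 == nv - 1) v0--;
          double fu = U - u0, fv = V - v0;
          const double* b = pa + u0 + (R_xlen_t)v0 * nu;
          double q = (b[0] * (1 - fu) + b[1] * fu) * (1 - fv) +
                     (b[nu] * (1 - fu) + b[nu + 1] * fu) * fv;
          ov[idx] += w2 * q;
        }
      }
    }
  }
  return out;
}

// Brute-force bilateral filter with a cubic window.
// [[Rcpp::export]]
NumericVector cpp_bilateral(NumericVector vol, double sigma_s_vox,
                            double sigma_r, int radius) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(vol.size());
  out.attr("dim") = d;
  const double* v = vol.begin();
  double* o = out.begin();
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double is2 = 1.0 / (2.0 * sigma_s_vox * sigma_s_vox);
  double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
  int r = radius;
  // spatial kernel lookup
  std::vector<double> ker((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  int t = 0;
  for (int dz = -r; dz <= r; dz++)
    for (int dy = -r; dy <= r; dy++)
      for (int dx = -r; dx <= r; dx++, t++)
        ker[t] = std::exp(-(dx * dx + dy * dy + dz * dz) * is2);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = x + (R_xlen_t)y * sy + (R_xlen_t)z * sz;
        double c = v[i], num = 0, den = 0;
        t = 0;
        for (int dz = -r; dz <= r; dz++) {
          int Z = z + dz;
          for (int dy = -r; dy <= r; dy++) {
            int Y = y + dy;
            for (int dx = -r; dx <= r; dx++, t++) {
              int X = x + dx;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz)
                continue;
              double val = v[X + (R_xlen_t)Y * sy + (R_xlen_t)Z * sz];
              double dd = val - c;
              double w = ker[t] * std::exp(-dd * dd * ir2);
              num += w * val;
              den += w;
            }
          }
        }
        o[i] = num / den;
      }
  return out;
}
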