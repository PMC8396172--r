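#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary 3-D mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns an integer grid, 0 = background, components numbered from 1 in
// scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  lab.attr("dim") = dm;
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  int nn = (int)ox.size();
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < ntot; start++) {
    if (!mask[start] || lab[start]) continue;
    next++;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / sy) % ny);
      int z = (int)(cur / sz);
      for (int q = 0; q < nn; q++) {
        int X = x + ox[q], Y = y + oy[q], Z = z + oz[q];
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        R_xlen_t nb = X + (R_xlen_t)Y * sy + (R_xlen_t)Z * sz;
        if (mask[nb] && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}

// Labels (sorted, unique) of components 26-adjacent to, or part of, the set
// marked by `seed` (a binary grid on the same lattice as `lab`).
// [[Rcpp::export]]
IntegerVector cpp_labels_touching(IntegerVector lab, IntegerVector seed) {
  IntegerVector dm = lab.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<bool> hit;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = x + (R_xlen_t)y * sy + (R_xlen_t)z * sz;
        if (!seed[i]) continue;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
              int l = lab[X + (R_xlen_t)Y * sy + (R_xlen_t)Z * sz];
              if (l > 0) {
                if ((int)hit.size() < l) hit.resize(l, false);
                hit[l - 1] = true;
              }
            }
      }
  std::vector<int> out;
  for (size_t i = 0; i < hit.size(); i++)
    if (hit[i]) out.push_back((int)i + 1);
  return wrap(out);
}
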