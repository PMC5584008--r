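#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3-D logical mask by breadth-first
// search. connectivity is 6 (face) or 26 (face+edge+corner). Returns an
// integer array of the same shape with 0 for background and 1..k for
// components, labeled in scan order (deterministic).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> offz, offy, offx;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  const int noff = (int)offz.size();

  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<R_xlen_t> stack;
  int cur = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int k = 0; k < noff; ++k) {
        int zz = z + offz[k], yy = y + offy[k], xx = x + offx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
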