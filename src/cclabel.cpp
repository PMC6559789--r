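#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a logical/integer mask by BFS.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims,
                         int connectivity = 26) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dz);
        off.push_back(dy);
        off.push_back(dx);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int comp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++comp;
    lab[s] = comp;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v % d1);
      int y = (int)((v / d1) % d2);
      int x = (int)(v / ((R_xlen_t)d1 * d2));
      for (size_t o = 0; o < off.size(); o += 3) {
        int zz = z + off[o], yy = y + off[o + 1], xx = x + off[o + 2];
        if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 || xx >= d3)
          continue;
        R_xlen_t w = (R_xlen_t)xx * d1 * d2 + (R_xlen_t)yy * d1 + zz;
        if (mask[w] && lab[w] == 0) {
          lab[w] = comp;
          queue.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
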