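#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 6-connected (face-adjacency) component labeling of a 3D logical mask.
// Labels are assigned in increasing order of each component's first voxel in
// R's linear (column-major) scan order, so numbering is deterministic.
// [[Rcpp::export(name = ".cpp_label6")]]
List cpp_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t ntot = (size_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);
  const int *m = LOGICAL(mask);
  int *lab = INTEGER(labels);
  int next = 0;
  std::vector<size_t> stack;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;

  for (size_t p = 0; p < ntot; ++p) {
    if (m[p] != 1 || lab[p] != 0) continue;
    ++next;
    lab[p] = next;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int x = (int)(q % nx);
      int y = (int)((q / sy) % ny);
      int z = (int)(q / sz);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t r = (size_t)xx + (size_t)yy * sy + (size_t)zz * sz;
        if (m[r] == 1 && lab[r] == 0) {
          lab[r] = next;
          stack.push_back(r);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["n_clusters"] = next);
}
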