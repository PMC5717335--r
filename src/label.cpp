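#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first search.
// mask: logical/int vector over a (nz, ny, nx) array, column-major, z fastest.
// connectivity: 6 (faces), 18 (faces+edges), or 26 (full neighbourhood).
// Labels are assigned 1..k in order of each component's first voxel in
// linear scan order, so the labeling is deterministic.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(IntegerVector mask, IntegerVector dims,
                         int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next_label;
    labels[i] = next_label;
    queue.clear();
    queue.push_back(i);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t cur = queue[head++];
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)yy * nz + (R_xlen_t)xx * nz * ny;
        if (mask[j] && !labels[j]) {
          labels[j] = next_label;
          queue.push_back(j);
        }
      }
    }
  }
  return labels;
}
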