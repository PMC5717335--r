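#include <Rcpp.h>
using namespace Rcpp;

// Dilate a voxel set by a structuring element of integer offsets, clipped to
// axis bounds. idx: 1-based linear indices into a (nz, ny, nx) column-major
// array (z fastest). offsets: (m x 3) integer matrix of (dz, dy, dx).
// bounds: (lo_z, hi_z, lo_y, hi_y, lo_x, hi_x), 1-based inclusive.
// Returns sorted unique 1-based linear indices.
// [[Rcpp::export(name = ".dilate_lin_cpp")]]
IntegerVector dilate_lin_cpp(IntegerVector idx, IntegerVector dims,
                             IntegerMatrix offsets, IntegerVector bounds) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> hit(n, 0);
  const int m = offsets.nrow();
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    R_xlen_t i0 = (R_xlen_t)idx[i] - 1;
    int z = (int)(i0 % nz) + 1;
    int y = (int)((i0 / nz) % ny) + 1;
    int x = (int)(i0 / ((R_xlen_t)nz * ny)) + 1;
    for (int k = 0; k < m; ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      if (zz < bounds[0] || zz > bounds[1] || yy < bounds[2] ||
          yy > bounds[3] || xx < bounds[4] || xx > bounds[5])
        continue;
      hit[(R_xlen_t)(zz - 1) + (R_xlen_t)(yy - 1) * nz +
          (R_xlen_t)(xx - 1) * nz * ny] = 1;
    }
  }
  R_xlen_t cnt = 0;
  for (R_xlen_t i = 0; i < n; ++i) cnt += hit[i];
  IntegerVector out(cnt);
  R_xlen_t p = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (hit[i]) out[p++] = (int)(i + 1);
  return out;  // ascending by construction
}
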