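#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D field at physical points (x, y, z) in
// micrometres. Values are interpolated between voxel centers; points less
// than half a voxel outside the centre lattice clamp to the border, points
// beyond the physical extent return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dims,
                            NumericVector voxel, NumericMatrix pts) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  int n = pts.nrow();
  NumericVector out(n);
  auto at = [&](int k, int j, int i) -> double {
    return arr[(R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
  };
  for (int p = 0; p < n; p++) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 ||
        x > nx * vx || y > ny * vy || z > nz * vz) {
      out[p] = NA_REAL;
      continue;
    }
    double fi = x / vx - 0.5, fj = y / vy - 0.5, fk = z / vz - 0.5;
    int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
    double ti = fi - i0, tj = fj - j0, tk = fk - k0;
    if (i0 < 0) { i0 = 0; ti = 0.0; }
    if (j0 < 0) { j0 = 0; tj = 0.0; }
    if (k0 < 0) { k0 = 0; tk = 0.0; }
    int i1 = i0 + 1, j1 = j0 + 1, k1 = k0 + 1;
    if (i1 >= nx) { i1 = nx - 1; ti = 0.0; }
    if (j1 >= ny) { j1 = ny - 1; tj = 0.0; }
    if (k1 >= nz) { k1 = nz - 1; tk = 0.0; }
    double c00 = at(k0, j0, i0) * (1 - ti) + at(k0, j0, i1) * ti;
    double c01 = at(k0, j1, i0) * (1 - ti) + at(k0, j1, i1) * ti;
    double c10 = at(k1, j0, i0) * (1 - ti) + at(k1, j0, i1) * ti;
    double c11 = at(k1, j1, i0) * (1 - ti) + at(k1, j1, i1) * ti;
    double c0 = c00 * (1 - tj) + c01 * tj;
    double c1 = c10 * (1 - tj) + c11 * tj;
    out[p] = c0 * (1 - tk) + c1 * tk;
  }
  return out;
}
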