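#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Arrays use dim = c(nz, ny, nx); linear index k + nz*(j + ny*i), 0-based.
// Physical coordinate of voxel (k, j, i) is ((k+0.5)*vz, (j+0.5)*vy, (i+0.5)*vx)
// reported as (z, y, x) in micrometres.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Rasterize a set of capsules (spheres when endpoints coincide) into a voxel
// field by exact point-to-segment distance in physical units. Voxel value is
// the max over overlapping primitives; edge_um is the anti-aliasing width of
// the intensity ramp across the primitive boundary (half coverage exactly at
// the nominal radius).
//
// seg columns: x1 y1 z1 x2 y2 z2 r1 r2 value
// [[Rcpp::export]]
NumericVector cpp_rasterize_capsules(IntegerVector dims, NumericVector voxel,
                                     NumericMatrix seg, double edge_um,
                                     double background) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n, background);

  for (int s = 0; s < seg.nrow(); s++) {
    const double x1 = seg(s, 0), y1 = seg(s, 1), z1 = seg(s, 2);
    const double x2 = seg(s, 3), y2 = seg(s, 4), z2 = seg(s, 5);
    const double r1 = seg(s, 6), r2 = seg(s, 7), val = seg(s, 8);
    const double rmax = std::max(r1, r2) + edge_um;

    const double ax = x2 - x1, ay = y2 - y1, az = z2 - z1;
    const double L2 = ax * ax + ay * ay + az * az;

    int i0 = (int)std::floor((std::min(x1, x2) - rmax) / vx - 0.5);
    int i1 = (int)std::ceil((std::max(x1, x2) + rmax) / vx - 0.5);
    int j0 = (int)std::floor((std::min(y1, y2) - rmax) / vy - 0.5);
    int j1 = (int)std::ceil((std::max(y1, y2) + rmax) / vy - 0.5);
    int k0 = (int)std::floor((std::min(z1, z2) - rmax) / vz - 0.5);
    int k1 = (int)std::ceil((std::max(z1, z2) + rmax) / vz - 0.5);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1); k1 = std::min(k1, nz - 1);

    for (int i = i0; i <= i1; i++) {
      const double px = (i + 0.5) * vx;
      for (int j = j0; j <= j1; j++) {
        const double py = (j + 0.5) * vy;
        for (int k = k0; k <= k1; k++) {
          const double pz = (k + 0.5) * vz;
          double t = 0.0;
          if (L2 > 0.0) {
            t = ((px - x1) * ax + (py - y1) * ay + (pz - z1) * az) / L2;
            t = clamp01(t);
          }
          const double cx = x1 + t * ax, cy = y1 + t * ay, cz = z1 + t * az;
          const double dx = px - cx, dy = py - cy, dz = pz - cz;
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          const double r = r1 + t * (r2 - r1);
          double cov;
          if (edge_um > 0.0) cov = clamp01(0.5 + (r - d) / edge_um);
          else cov = (d <= r) ? 1.0 : 0.0;
          if (cov > 0.0) {
            R_xlen_t idx = (R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
            double v = val * cov;
            if (v > out[idx]) out[idx] = v;
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
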