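#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each grid cell (8 voxel centers)
// is split into 6 tetrahedra sharing the main diagonal; the level surface is
// linearly interpolated along tetrahedron edges. Anisotropic voxel spacing
// is honoured because vertices live in physical coordinates.
// Field values outside the array are treated as `outside` (below the level
// for a bright object), so objects touching the border are closed.

static inline double triarea(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1],
                 u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector arr, IntegerVector dims,
                           NumericVector voxel, double level, double outside) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  auto val = [&](int k, int j, int i) -> double {
    if (k < 0 || k >= nz || j < 0 || j >= ny || i < 0 || i >= nx) return outside;
    return arr[(R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
  };
  // cube corner offsets (i, j, k): classic numbering with main diagonal 0-6
  static const int corner[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
  };
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
  };
  double area = 0.0;
  double P[8][3], V[8];
  // iterate over cells whose corner 0 is voxel (i-?,...) include a 1-cell
  // border so surfaces at the array edge are closed
  for (int i = -1; i < nx; i++)
    for (int j = -1; j < ny; j++)
      for (int k = -1; k < nz; k++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int ic = i + corner[c][0], jc = j + corner[c][1], kc = k + corner[c][2];
          V[c] = val(kc, jc, ic);
          P[c][0] = (ic + 0.5) * vx;
          P[c][1] = (jc + 0.5) * vy;
          P[c][2] = (kc + 0.5) * vz;
          if (V[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          const int *T = tets[t];
          int inside[4], nin = 0, nout = 0, outv[4];
          for (int c = 0; c < 4; c++) {
            if (V[T[c]] >= level) inside[nin++] = T[c];
            else outv[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          // interpolated point on edge (a inside, b outside)
          auto interp = [&](int a, int b, double out[3]) {
            double denom = V[b] - V[a];
            double tt = denom != 0.0 ? (level - V[a]) / denom : 0.5;
            if (tt < 0.0) tt = 0.0;
            if (tt > 1.0) tt = 1.0;
            for (int d = 0; d < 3; d++) out[d] = P[a][d] + tt * (P[b][d] - P[a][d]);
          };
          if (nin == 1) {
            double p0[3], p1[3], p2[3];
            interp(inside[0], outv[0], p0);
            interp(inside[0], outv[1], p1);
            interp(inside[0], outv[2], p2);
            area += triarea(p0, p1, p2);
          } else if (nin == 3) {
            double p0[3], p1[3], p2[3];
            interp(inside[0], outv[0], p0);
            interp(inside[1], outv[0], p1);
            interp(inside[2], outv[0], p2);
            area += triarea(p0, p1, p2);
          } else { // 2-2: quad split into two triangles
            double p00[3], p01[3], p10[3], p11[3];
            interp(inside[0], outv[0], p00);
            interp(inside[0], outv[1], p01);
            interp(inside[1], outv[0], p10);
            interp(inside[1], outv[1], p11);
            area += triarea(p00, p01, p10);
            area += triarea(p01, p11, p10);
          }
        }
      }
  return area;
}
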