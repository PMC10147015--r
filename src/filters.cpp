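#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Separable Gaussian blur with per-axis sigma in voxel units; reflecting
// boundary. dim = c(nz, ny, nx), column-major.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector arr, IntegerVector dims,
                                NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nd[3] = {nz, ny, nx};
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(arr.begin(), arr.end()), b(n);

  // stride of axis 0 (z) is 1, axis 1 (y) is nz, axis 2 (x) is nz*ny
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0.0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0.0;
    for (int t = -rad; t <= rad; t++) {
      ker[t + rad] = std::exp(-0.5 * (t * t) / (s * s));
      sum += ker[t + rad];
    }
    for (double &w : ker) w /= sum;

    const int len = nd[ax];
    const R_xlen_t str = strides[ax];
    // iterate over all lines along this axis
    const R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; line++) {
      // compute base index of this line
      R_xlen_t rem = line, base = 0;
      for (int d = 0; d < 3; d++) {
        if (d == ax) continue;
        R_xlen_t sz = nd[d];
        R_xlen_t coord = rem % sz;
        rem /= sz;
        base += coord * strides[d];
      }
      for (int p = 0; p < len; p++) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; t++) {
          int q = p + t;
          if (q < 0) q = -q - 1;            // reflect
          if (q >= len) q = 2 * len - q - 1;
          if (q < 0) q = 0;                 // very short axes
          if (q >= len) q = len - 1;
          acc += ker[t + rad] * a[base + (R_xlen_t)q * str];
        }
        b[base + (R_xlen_t)p * str] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Discrete Laplacian with physical voxel spacing (replicate boundary).
// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector arr, IntegerVector dims,
                            NumericVector voxel) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  const double wz = 1.0 / (voxel[0] * voxel[0]);
  const double wy = 1.0 / (voxel[1] * voxel[1]);
  const double wx = 1.0 / (voxel[2] * voxel[2]);
  auto at = [&](int k, int j, int i) -> double {
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    return arr[(R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
  };
  for (int i = 0; i < nx; i++)
    for (int j = 0; j < ny; j++)
      for (int k = 0; k < nz; k++) {
        double c = at(k, j, i);
        double l =
          wz * (at(k - 1, j, i) + at(k + 1, j, i) - 2.0 * c) +
          wy * (at(k, j - 1, i) + at(k, j + 1, i) - 2.0 * c) +
          wx * (at(k, j, i - 1) + at(k, j, i + 1) - 2.0 * c);
        out[(R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)] = l;
      }
  out.attr("dim") = dims;
  return out;
}

// Local maxima of a 3D field over the 26-neighborhood, above a threshold.
// Plateaus report their (z,y,x)-lexicographically first voxel: a voxel wins
// if it is >= all neighbors and strictly > all lexicographically earlier
// equal-valued neighbors. With tol > 0 the comparison is ridge-tolerant:
// a voxel also qualifies when >= (1 - tol) * max(neighbors) (used for seed
// points along tube ridges, where the response is nearly flat on-axis).
// Returns 0-based (k, j, i) rows ordered by (z,y,x).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector arr, IntegerVector dims,
                               double threshold, double tol) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> kk, jj, ii;
  auto idx = [&](int k, int j, int i) {
    return (R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
  };
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double c = arr[idx(k, j, i)];
        if (!(c > threshold)) continue;
        double nbmax = -std::numeric_limits<double>::infinity();
        bool earlier_ge = false;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (!dk && !dj && !di) continue;
              int k2 = k + dk, j2 = j + dj, i2 = i + di;
              if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny ||
                  i2 < 0 || i2 >= nx) continue;
              double v = arr[idx(k2, j2, i2)];
              if (v > nbmax) nbmax = v;
              // lexicographic (z,y,x): earlier if k2<k, or k2==k && j2<j, ...
              bool earlier = (k2 < k) || (k2 == k && (j2 < j || (j2 == j && i2 < i)));
              if (earlier && v >= c) earlier_ge = true;
            }
        bool ok;
        if (tol > 0.0) {
          ok = (c >= (1.0 - tol) * nbmax);
        } else {
          ok = (c >= nbmax) && !earlier_ge;
        }
        if (ok) { kk.push_back(k); jj.push_back(j); ii.push_back(i); }
      }
  IntegerMatrix out(kk.size(), 3);
  for (size_t r = 0; r < kk.size(); r++) {
    out(r, 0) = kk[r]; out(r, 1) = jj[r]; out(r, 2) = ii[r];
  }
  return out;
}
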