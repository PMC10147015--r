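#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a logical mask. Labels are assigned in
// order of each component's (z,y,x)-lexicographically first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  auto idx = [&](int k, int j, int i) {
    return (R_xlen_t)k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
  };
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t p = idx(k, j, i);
        if (!mask[p] || lab[p]) continue;
        next++;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int iq = (int)(q / ((R_xlen_t)nz * ny));
          int jq = (int)((q / nz) % ny);
          int kq = (int)(q % nz);
          for (int dk = -1; dk <= 1; dk++)
            for (int dj = -1; dj <= 1; dj++)
              for (int di = -1; di <= 1; di++) {
                if (!dk && !dj && !di) continue;
                int k2 = kq + dk, j2 = jq + dj, i2 = iq + di;
                if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny ||
                    i2 < 0 || i2 >= nx) continue;
                R_xlen_t r = idx(k2, j2, i2);
                if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
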