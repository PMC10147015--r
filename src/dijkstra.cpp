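#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-source Dijkstra on the 26-connected voxel grid with anisotropic
// physical step lengths. Per-voxel multiplicative cost factors are supplied
// by the caller (intensity-weighted autopath cost; +Inf excludes a voxel).
// Edge weight between adjacent voxels a,b = step_length * (f[a] + f[b]) / 2.
// When `targets` is nonempty the search stops once every target voxel is
// settled (background voxels carry a large cost penalty, so they are popped
// last and mostly never explored). Returns geodesic cost and predecessor
// (0-based linear index, -1 = none).
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector factor, IntegerVector dims,
                  NumericVector voxel, int source, IntegerVector targets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, -1);

  // precompute the 26 neighbor offsets and physical step lengths
  int offs[26][3];
  double slen[26];
  R_xlen_t doff[26];
  int m = 0;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (!dk && !dj && !di) continue;
        offs[m][0] = dk; offs[m][1] = dj; offs[m][2] = di;
        slen[m] = std::sqrt(dk * dk * vz * vz + dj * dj * vy * vy + di * di * vx * vx);
        doff[m] = (R_xlen_t)dk + (R_xlen_t)nz * (dj + (R_xlen_t)ny * di);
        m++;
      }

  std::vector<char> isTarget(n, 0);
  int remaining = 0;
  for (int t = 0; t < targets.size(); t++) {
    if (!isTarget[targets[t]]) { isTarget[targets[t]] = 1; remaining++; }
  }
  const bool earlyStop = remaining > 0;

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  if (R_finite(factor[source])) {
    dist[source] = 0.0;
    pq.push(QE(0.0, source));
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first;
    R_xlen_t u = top.second;
    if (d > dist[u]) continue;
    if (earlyStop && isTarget[u]) {
      isTarget[u] = 0;
      if (--remaining == 0) break;
    }
    int iu = (int)(u / ((R_xlen_t)nz * ny));
    int ju = (int)((u / nz) % ny);
    int ku = (int)(u % nz);
    double fu = factor[u];
    for (int e = 0; e < 26; e++) {
      int k2 = ku + offs[e][0], j2 = ju + offs[e][1], i2 = iu + offs[e][2];
      if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny || i2 < 0 || i2 >= nx)
        continue;
      R_xlen_t v = u + doff[e];
      double fv = factor[v];
      if (!R_finite(fv)) continue;
      double nd = d + slen[e] * 0.5 * (fu + fv);
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = (int)u;
        pq.push(QE(nd, v));
      }
    }
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}
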