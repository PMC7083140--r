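#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e30;

// Exact 1D squared distance transform (lower envelope of parabolas),
// generalised to a non-unit grid spacing w.  f holds squared distances
// (BIG where no feature has been seen yet); d receives the update.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double pq = q * w;
    double s;
    for (;;) {
      double pv = v[k] * w;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2.0 * (pq - pv));
      if (s > z[k]) break;
      k--;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double pq = q * w;
    while (z[k + 1] < pq) k++;
    double dp = pq - v[k] * w;
    d[q] = dp * dp + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), g(nmax);

  // pass along dim 1 (stride 1)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t off = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; i++) f[i] = d[off + i];
      dt1d(f, g, n1, spacing[0]);
      for (int i = 0; i < n1; i++) d[off + i] = g[i];
    }
  // pass along dim 2 (stride n1)
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t off = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; j++) f[j] = d[off + (R_xlen_t)j * n1];
      dt1d(f, g, n2, spacing[1]);
      for (int j = 0; j < n2; j++) d[off + (R_xlen_t)j * n1] = g[j];
    }
  // pass along dim 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t off = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; k++) f[k] = d[off + (R_xlen_t)k * s3];
      dt1d(f, g, n3, spacing[2]);
      for (int k = 0; k < n3; k++) d[off + (R_xlen_t)k * s3] = g[k];
    }
  return d;
}

// Naive all-pairs minimum distance: for each row of `cell` (physical
// coordinates, micrometers) the minimum Euclidean distance to any row of
// `tub`.  Deliberately exhaustive (with cheap per-axis pruning) so it can
// serve as an independent oracle for the transform above.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix cell, NumericMatrix tub) {
  const int nc = cell.nrow(), nt = tub.nrow();
  NumericVector out(nc);
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int t = 0; t < nt; t++) {
    tx[t] = tub(t, 0);
    ty[t] = tub(t, 1);
    tz[t] = tub(t, 2);
  }
  for (int c = 0; c < nc; c++) {
    const double cx = cell(c, 0), cy = cell(c, 1), cz = cell(c, 2);
    double best = BIG;
    for (int t = 0; t < nt; t++) {
      double dx = tx[t] - cx;
      double dd = dx * dx;
      if (dd >= best) continue;
      double dy = ty[t] - cy;
      dd += dy * dy;
      if (dd >= best) continue;
      double dz = tz[t] - cz;
      dd += dz * dz;
      if (dd < best) best = dd;
    }
    out[c] = std::sqrt(best);
  }
  return out;
}

// Region reachable from the array border through non-blocked voxels
// (6-connected breadth-first fill).
// [[Rcpp::export]]
LogicalVector cpp_flood_outside(LogicalVector blocked, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector vis(n);
  std::queue<R_xlen_t> q;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        if (i > 0 && i < n1 - 1 && j > 0 && j < n2 - 1 &&
            k > 0 && k < n3 - 1)
          continue;
        R_xlen_t idx = (R_xlen_t)k * s3 + (R_xlen_t)j * s2 + i;
        if (!blocked[idx] && !vis[idx]) {
          vis[idx] = true;
          q.push(idx);
        }
      }
  while (!q.empty()) {
    R_xlen_t idx = q.front();
    q.pop();
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / s3);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; m++) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t nb = (R_xlen_t)kk * s3 + (R_xlen_t)jj * s2 + ii;
      if (!blocked[nb] && !vis[nb]) {
        vis[nb] = true;
        q.push(nb);
      }
    }
  }
  return vis;
}
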