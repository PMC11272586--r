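#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Threshold-free cluster enhancement on an arbitrary voxel adjacency
// (CSR neighbour lists, 0-based).  Only the positive part of the statistic
// map is enhanced; callers run the negated map for the opposite tail.
//
// TFCE(v) = sum over thresholds h = dh, 2dh, ..., max of
//           e_v(h)^E * h^H * dh,
// where e_v(h) is the size of the connected supra-threshold component
// containing v at height h.  Components are grown incrementally with a
// union-find while sweeping thresholds from high to low.

struct UF {
  std::vector<int> parent, size;
  UF(int n) : parent(n), size(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    while (parent[v] != r) { int nxt = parent[v]; parent[v] = r; v = nxt; }
    return r;
  }
  // returns surviving root
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
    return a;
  }
};

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector nbr, IntegerVector ptr,
                       double H, double Epow, int nsteps) {
  int V = stat.size();
  NumericVector score(V);
  double mx = 0.0;
  for (int i = 0; i < V; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || nsteps < 1) return score;
  double dh = mx / nsteps;

  std::vector<int> order;
  order.reserve(V);
  for (int i = 0; i < V; ++i) if (stat[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  UF uf(V);
  std::vector<bool> active(V, false);
  std::vector<int> stamp(V, -1);
  std::vector<double> contrib(V, 0.0);
  size_t k = 0;
  for (int j = nsteps; j >= 1; --j) {
    double h = j * dh;
    while (k < order.size() && stat[order[k]] >= h) {
      int v = order[k++];
      active[v] = true;
      uf.size[v] = 1;
      for (int q = ptr[v]; q < ptr[v + 1]; ++q) {
        int w = nbr[q];
        if (active[w]) uf.unite(v, w);
      }
    }
    double hterm = std::pow(h, H) * dh;
    for (size_t a = 0; a < k; ++a) {
      int v = order[a];
      int r = uf.find(v);
      if (stamp[r] != j) {
        contrib[r] = std::pow((double)uf.size[r], Epow) * hterm;
        stamp[r] = j;
      }
      score[v] += contrib[r];
    }
  }
  return score;
}

// Maximum TFCE score per column of a statistic matrix (voxels x maps),
// used for the permutation null of the map-wide maximum.  Tracks, per
// union-find component, the best accumulated score over its local peaks;
// the map-wide maximum TFCE is attained at one of those peaks.
// [[Rcpp::export]]
NumericVector tfce_max_cpp(NumericMatrix stats, IntegerVector nbr,
                           IntegerVector ptr, double H, double Epow,
                           int nsteps) {
  int V = stats.nrow(), M = stats.ncol();
  NumericVector out(M);
  std::vector<bool> active(V);
  std::vector<double> best(V);
  // voxels bucketed by the threshold step at which they activate
  std::vector<int> bucket_head(nsteps + 1);
  std::vector<int> bucket_next(V);
  for (int m = 0; m < M; ++m) {
    double mx = 0.0;
    for (int i = 0; i < V; ++i) if (stats(i, m) > mx) mx = stats(i, m);
    if (mx <= 0.0) { out[m] = 0.0; continue; }
    double dh = mx / nsteps;
    std::fill(bucket_head.begin(), bucket_head.end(), -1);
    for (int i = 0; i < V; ++i) {
      double s = stats(i, m);
      if (s <= 0.0) continue;
      int j = (int)std::floor(s / dh);
      if (j < 1) continue;          // below the first threshold
      if (j > nsteps) j = nsteps;
      bucket_next[i] = bucket_head[j];
      bucket_head[j] = i;
    }
    UF uf(V);
    std::fill(active.begin(), active.end(), false);
    std::vector<int> roots;
    for (int j = nsteps; j >= 1; --j) {
      double h = j * dh;
      for (int v = bucket_head[j]; v != -1; v = bucket_next[v]) {
        active[v] = true;
        uf.size[v] = 1;
        best[v] = 0.0;
        roots.push_back(v);
        for (int q = ptr[v]; q < ptr[v + 1]; ++q) {
          int w = nbr[q];
          if (active[w]) {
            int ra = uf.find(v), rb = uf.find(w);
            if (ra != rb) {
              double b2 = std::max(best[ra], best[rb]);
              int r = uf.unite(ra, rb);
              best[r] = b2;
            }
          }
        }
      }
      double hterm = std::pow(h, H) * dh;
      // iterate live roots, dropping merged ones
      size_t w = 0;
      for (size_t a = 0; a < roots.size(); ++a) {
        int r = roots[a];
        if (uf.parent[r] != r) continue; // absorbed
        best[r] += std::pow((double)uf.size[r], Epow) * hterm;
        roots[w++] = r;
      }
      roots.resize(w);
    }
    double mmax = 0.0;
    for (size_t a = 0; a < roots.size(); ++a)
      mmax = std::max(mmax, best[roots[a]]);
    out[m] = mmax;
  }
  return out;
}
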