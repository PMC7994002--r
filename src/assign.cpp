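#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Optimal assignment (Kuhn-Munkres with potentials / shortest augmenting
// paths). Requires nrow <= ncol; the R wrapper transposes or pads as needed.
// Returns, for each row, the 1-based column it is matched to.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("cpp_hungarian: need nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// DBSCAN on a small point set (rows = points, physical coordinates). A point
// is core when its eps-neighbourhood, itself included, holds >= min_samples
// points. Returns cluster ids 1..k, 0 for noise. Brute-force neighbourhoods:
// per-label point sets here are small.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_samples) {
  const int n = pts.nrow(), d = pts.ncol();
  const double eps2 = eps * eps;
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].push_back(i);
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = pts(i, c) - pts(j, c);
        s += t * t;
      }
      if (s <= eps2) {
        nb[i].push_back(j);
        nb[j].push_back(i);
      }
    }
  }
  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) core[i] = (int)nb[i].size() >= min_samples;

  IntegerVector lab(n, 0);
  std::vector<char> visited(n, 0);
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i] || !core[i]) continue;
    ++cur;
    std::queue<int> q;
    q.push(i);
    visited[i] = 1;
    lab[i] = cur;
    while (!q.empty()) {
      const int p = q.front();
      q.pop();
      if (!core[p]) continue;  // border point: claimed but not expanded
      for (int t : nb[p]) {
        if (lab[t] == 0) lab[t] = cur;
        if (!visited[t]) {
          visited[t] = 1;
          q.push(t);
        }
      }
    }
  }
  return lab;
}

// Distance to the k-th nearest neighbour (self excluded) for every point.
// [[Rcpp::export]]
NumericVector cpp_knn_kth(NumericMatrix pts, int k) {
  const int n = pts.nrow(), d = pts.ncol();
  if (k >= n) stop("cpp_knn_kth: need k < number of points");
  NumericVector out(n);
  std::vector<double> dist(n - 1);
  for (int i = 0; i < n; ++i) {
    int t = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      dist[t++] = s;
    }
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    out[i] = std::sqrt(dist[k - 1]);
  }
  return out;
}
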