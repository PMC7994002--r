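#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Entry {
  double priority;
  long long age;
  R_xlen_t idx;
  int label;
  R_xlen_t origin;  // seed voxel the flood started from, for the compactness term
};

struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.age > b.age;  // earlier insertion wins ties
  }
};

}  // namespace

// Compact seeded watershed. Floods ascending `elev` from the seed voxels,
// restricted to `mask`, with an additive penalty `compactness * d^2` where d is
// the Euclidean voxel distance to the flood's seed origin. Face connectivity.
// Deterministic: ties broken by insertion order. Mask voxels unreachable from
// any seed stay 0 (the caller decides how to fill them).
// [[Rcpp::export]]
IntegerVector cpp_compact_watershed(IntegerVector seeds, NumericVector elev,
                                    LogicalVector mask, IntegerVector dim,
                                    double compactness) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t off3 = (R_xlen_t)d1 * d2;
  IntegerVector out(n);

  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> pq;
  long long age = 0;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (seeds[idx] != 0 && mask[idx]) {
      out[idx] = seeds[idx];
      pq.push(Entry{elev[idx], age++, idx, seeds[idx], idx});
    }
  }

  while (!pq.empty()) {
    Entry e = pq.top();
    pq.pop();
    const R_xlen_t idx = e.idx;
    const int i = (int)(idx % d1);
    const int j = (int)((idx / d1) % d2);
    const int k = (int)(idx / off3);
    const int oi = (int)(e.origin % d1);
    const int oj = (int)((e.origin / d1) % d2);
    const int ok_ = (int)(e.origin / off3);

    const R_xlen_t nb[6] = {idx - 1, idx + 1, idx - d1, idx + d1,
                            idx - off3, idx + off3};
    const bool inb[6] = {i > 0, i < d1 - 1, j > 0, j < d2 - 1, k > 0,
                         k < d3 - 1};
    const int ni[6] = {i - 1, i + 1, i, i, i, i};
    const int nj[6] = {j, j, j - 1, j + 1, j, j};
    const int nk[6] = {k, k, k, k, k - 1, k + 1};
    for (int t = 0; t < 6; ++t) {
      if (!inb[t]) continue;
      const R_xlen_t m = nb[t];
      if (!mask[m] || out[m] != 0) continue;
      out[m] = e.label;
      double pen = 0.0;
      if (compactness > 0) {
        const double a = ni[t] - oi, b = nj[t] - oj, c = nk[t] - ok_;
        pen = compactness * (a * a + b * b + c * c);
      }
      pq.push(Entry{elev[m] + pen, age++, m, e.label, e.origin});
    }
  }

  out.attr("dim") = dim;
  return out;
}
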