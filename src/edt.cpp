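#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for +inf so the parabola-envelope arithmetic stays finite.
static const double BIG = 1e30;

// Felzenszwalb & Huttenlocher 1D squared distance transform along one line,
// with grid step weight w2 = spacing^2 for that axis.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w2, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance to the nearest TRUE voxel, spacing-aware.
// Voxels with no feature anywhere come back as +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : BIG;

  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  int maxd = std::max(d1, std::max(d2, d3));
  std::vector<double> f(maxd), dl(maxd), z(maxd + 1);
  std::vector<int> v(maxd);

  for (int ax = 0; ax < 3; ++ax) {
    const int na = dims[ax];
    if (na <= 1) continue;
    const double w2 = spacing[ax] * spacing[ax];
    const int b1 = (ax == 0) ? 1 : 0;
    const int b2 = (ax == 2) ? 1 : 2;
    const int nb1 = dims[b1], nb2 = dims[b2];
    const R_xlen_t sa = strides[ax], s1 = strides[b1], s2 = strides[b2];
    for (int j2 = 0; j2 < nb2; ++j2) {
      for (int j1 = 0; j1 < nb1; ++j1) {
        const R_xlen_t base = j1 * s1 + j2 * s2;
        for (int q = 0; q < na; ++q) f[q] = out[base + q * sa];
        dt1d(f, dl, na, w2, v, z);
        for (int q = 0; q < na; ++q) out[base + q * sa] = dl[q];
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= BIG * 0.5) out[i] = R_PosInf;
  out.attr("dim") = dim;
  return out;
}

// Fill each TRUE `target` voxel that is unlabeled with the label of its nearest
// (spacing-weighted Euclidean) labeled voxel. Equidistant donors are broken by
// the lowest linear index. Donor candidates are restricted to labeled voxels
// with at least one unlabeled face neighbour (the nearest labeled voxel to an
// outside query always lies on that boundary).
// [[Rcpp::export]]
IntegerVector cpp_inpaint(IntegerVector labels, LogicalVector target,
                          IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector out = clone(labels);

  std::vector<R_xlen_t> donors;
  donors.reserve(1024);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (labels[idx] == 0) continue;
        bool boundary =
          (i > 0 && labels[idx - 1] == 0) ||
          (i < d1 - 1 && labels[idx + 1] == 0) ||
          (j > 0 && labels[idx - d1] == 0) ||
          (j < d2 - 1 && labels[idx + d1] == 0) ||
          (k > 0 && labels[idx - (R_xlen_t)d1 * d2] == 0) ||
          (k < d3 - 1 && labels[idx + (R_xlen_t)d1 * d2] == 0);
        if (boundary) donors.push_back(idx);
      }
  if (donors.empty()) {
    // Labeled voxels exist but have no unlabeled neighbours; every target voxel
    // must already be labeled (or there are no labels at all -> caller errors).
    return out;
  }

  const double w1 = spacing[0] * spacing[0];
  const double w2 = spacing[1] * spacing[1];
  const double w3 = spacing[2] * spacing[2];
  const size_t nd = donors.size();
  std::vector<int> di(nd), dj(nd), dk(nd);
  for (size_t t = 0; t < nd; ++t) {
    R_xlen_t idx = donors[t];
    di[t] = (int)(idx % d1);
    dj[t] = (int)((idx / d1) % d2);
    dk[t] = (int)(idx / ((R_xlen_t)d1 * d2));
  }

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!target[idx] || labels[idx] != 0) continue;
    const int i = (int)(idx % d1);
    const int j = (int)((idx / d1) % d2);
    const int k = (int)(idx / ((R_xlen_t)d1 * d2));
    double best = R_PosInf;
    R_xlen_t bestIdx = -1;
    for (size_t t = 0; t < nd; ++t) {
      const double a = di[t] - i, b = dj[t] - j, c = dk[t] - k;
      const double dd = w1 * a * a + w2 * b * b + w3 * c * c;
      if (dd < best) {  // strict: ties keep the earlier (lower linear index) donor
        best = dd;
        bestIdx = donors[t];
      }
    }
    out[idx] = labels[bestIdx];
  }
  out.attr("dim") = dim;
  return out;
}
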