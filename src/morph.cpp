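#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int d1, int d2) {
  return i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
}

// Greyscale 3x3(x3) neighbourhood min or max.
// connectivity 6: centre + face neighbours (the Euclidean ball of radius 1);
// connectivity 26: full box (separable). Out-of-bounds neighbours are ignored.
// [[Rcpp::export]]
NumericVector cpp_minmax3(NumericVector x, IntegerVector dim, int connectivity,
                          bool take_max) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);

  if (connectivity == 26) {
    NumericVector cur = clone(x);
    const int dims[3] = {d1, d2, d3};
    const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
    for (int ax = 0; ax < 3; ++ax) {
      const int na = dims[ax];
      NumericVector nxt(n);
      const int b1 = (ax == 0) ? 1 : 0;
      const int b2 = (ax == 2) ? 1 : 2;
      const R_xlen_t sa = strides[ax], s1 = strides[b1], s2 = strides[b2];
      for (int j2 = 0; j2 < dims[b2]; ++j2)
        for (int j1 = 0; j1 < dims[b1]; ++j1) {
          const R_xlen_t base = j1 * s1 + j2 * s2;
          for (int q = 0; q < na; ++q) {
            double v = cur[base + q * sa];
            if (q > 0) {
              double w = cur[base + (q - 1) * sa];
              v = take_max ? std::max(v, w) : std::min(v, w);
            }
            if (q < na - 1) {
              double w = cur[base + (q + 1) * sa];
              v = take_max ? std::max(v, w) : std::min(v, w);
            }
            nxt[base + q * sa] = v;
          }
        }
      cur = nxt;
    }
    out = cur;
  } else {
    const R_xlen_t off1 = 1, off2 = d1, off3 = (R_xlen_t)d1 * d2;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          const R_xlen_t idx = lin(i, j, k, d1, d2);
          double v = x[idx];
          if (i > 0)       v = take_max ? std::max(v, (double)x[idx - off1]) : std::min(v, (double)x[idx - off1]);
          if (i < d1 - 1)  v = take_max ? std::max(v, (double)x[idx + off1]) : std::min(v, (double)x[idx + off1]);
          if (j > 0)       v = take_max ? std::max(v, (double)x[idx - off2]) : std::min(v, (double)x[idx - off2]);
          if (j < d2 - 1)  v = take_max ? std::max(v, (double)x[idx + off2]) : std::min(v, (double)x[idx + off2]);
          if (k > 0)       v = take_max ? std::max(v, (double)x[idx - off3]) : std::min(v, (double)x[idx - off3]);
          if (k < d3 - 1)  v = take_max ? std::max(v, (double)x[idx + off3]) : std::min(v, (double)x[idx + off3]);
          out[idx] = v;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Binary erosion by the face-connected cross. `border_fg` controls whether
// voxels outside the array count as foreground (TRUE keeps masks touching the
// array border intact) or background (TRUE surface at the border).
// [[Rcpp::export]]
LogicalVector cpp_erode_cross(LogicalVector mask, IntegerVector dim,
                              bool border_fg) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n);
  const R_xlen_t off3 = (R_xlen_t)d1 * d2;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t idx = lin(i, j, k, d1, d2);
        bool v = mask[idx];
        if (v) {
          v = (i > 0 ? (bool)mask[idx - 1] : border_fg) &&
              (i < d1 - 1 ? (bool)mask[idx + 1] : border_fg) &&
              (j > 0 ? (bool)mask[idx - d1] : border_fg) &&
              (j < d2 - 1 ? (bool)mask[idx + d1] : border_fg) &&
              (k > 0 ? (bool)mask[idx - off3] : border_fg) &&
              (k < d3 - 1 ? (bool)mask[idx + off3] : border_fg);
        }
        out[idx] = v;
      }
  out.attr("dim") = dim;
  return out;
}

// Union over labels of (label minus its cross-erosion): a voxel is surface iff
// it is labeled and any face neighbour (or the array border) carries a
// different value.
// [[Rcpp::export]]
LogicalVector cpp_label_surfaces(IntegerVector labels, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n);
  const R_xlen_t off3 = (R_xlen_t)d1 * d2;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t idx = lin(i, j, k, d1, d2);
        const int v = labels[idx];
        if (v == 0) { out[idx] = false; continue; }
        bool surf =
          (i == 0 || labels[idx - 1] != v) ||
          (i == d1 - 1 || labels[idx + 1] != v) ||
          (j == 0 || labels[idx - d1] != v) ||
          (j == d2 - 1 || labels[idx + d1] != v) ||
          (k == 0 || labels[idx - off3] != v) ||
          (k == d3 - 1 || labels[idx + off3] != v);
        out[idx] = surf;
      }
  out.attr("dim") = dim;
  return out;
}

// Discrete Laplacian, 3-point stencil per axis (sum of face neighbours minus
// 6x centre), replicate border so a uniform field maps to zero.
// [[Rcpp::export]]
NumericVector cpp_laplace3(NumericVector x, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  const R_xlen_t off3 = (R_xlen_t)d1 * d2;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t idx = lin(i, j, k, d1, d2);
        const double c = x[idx];
        double s = 0.0;
        s += (i > 0) ? x[idx - 1] : c;
        s += (i < d1 - 1) ? x[idx + 1] : c;
        s += (j > 0) ? x[idx - d1] : c;
        s += (j < d2 - 1) ? x[idx + d1] : c;
        s += (k > 0) ? x[idx - off3] : c;
        s += (k < d3 - 1) ? x[idx + off3] : c;
        out[idx] = s - 6.0 * c;
      }
  out.attr("dim") = dim;
  return out;
}

// Connected components of a mask (face connectivity), labels 1..n by first
// encounter in linear scan order. Used for structure finding in 2D planes.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector out(n);
  const R_xlen_t off3 = (R_xlen_t)d1 * d2;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    out[s] = cur;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      const int i = (int)(idx % d1);
      const int j = (int)((idx / d1) % d2);
      const int k = (int)(idx / off3);
      const R_xlen_t nb[6] = {idx - 1, idx + 1, idx - d1, idx + d1,
                              idx - off3, idx + off3};
      const bool ok[6] = {i > 0, i < d1 - 1, j > 0, j < d2 - 1, k > 0,
                          k < d3 - 1};
      for (int t = 0; t < 6; ++t) {
        if (ok[t] && mask[nb[t]] && out[nb[t]] == 0) {
          out[nb[t]] = cur;
          stack.push_back(nb[t]);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
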