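#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// reflect (symmetric, edge included once): ... c b a | a b c ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - 1 - i;
}

// Separable 3D Gaussian, sigma per axis in voxels, kernel truncated at
// `truncate` sigmas, symmetric boundary reflection.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, IntegerVector dim,
                          NumericVector sigma, double truncate) {
  const int dims[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t strides[3] = {1, (R_xlen_t)dims[0],
                               (R_xlen_t)dims[0] * dims[1]};
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector cur = clone(x);

  for (int ax = 0; ax < 3; ++ax) {
    const double sg = sigma[ax];
    if (sg <= 0 || dims[ax] <= 1) continue;
    const int r = std::max(1, (int)std::ceil(truncate * sg));
    std::vector<double> kern(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      sum += kern[t + r];
    }
    for (double& w : kern) w /= sum;

    NumericVector nxt(n);
    const int na = dims[ax];
    const int b1 = (ax == 0) ? 1 : 0;
    const int b2 = (ax == 2) ? 1 : 2;
    const R_xlen_t sa = strides[ax], s1 = strides[b1], s2 = strides[b2];
    std::vector<double> line(na);
    for (int j2 = 0; j2 < dims[b2]; ++j2)
      for (int j1 = 0; j1 < dims[b1]; ++j1) {
        const R_xlen_t base = j1 * s1 + j2 * s2;
        for (int q = 0; q < na; ++q) line[q] = cur[base + q * sa];
        for (int q = 0; q < na; ++q) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t)
            acc += kern[t + r] * line[reflect(q + t, na)];
          nxt[base + q * sa] = acc;
        }
      }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Scale-space peaks of a 4D response stack (dims: space x space x space x
// n_scales). A voxel is a peak when its response exceeds `threshold` and is >=
// every neighbour in the 3x3x3 spatial box at its own scale and the adjacent
// scales. Returns a matrix with 0-based (i, j, k), scale index, response.
// [[Rcpp::export]]
NumericMatrix cpp_blob_peaks(NumericVector stack, IntegerVector dim4,
                             double threshold) {
  const int d1 = dim4[0], d2 = dim4[1], d3 = dim4[2], ns = dim4[3];
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> rows;

  for (int sc = 0; sc < ns; ++sc) {
    const R_xlen_t sbase = (R_xlen_t)sc * nvox;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          const R_xlen_t idx = sbase + i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
          const double v = stack[idx];
          if (!(v > threshold)) continue;
          bool peak = true;
          for (int dsc = -1; dsc <= 1 && peak; ++dsc) {
            const int s2 = sc + dsc;
            if (s2 < 0 || s2 >= ns) continue;
            const R_xlen_t b2 = (R_xlen_t)s2 * nvox;
            for (int dk = -1; dk <= 1 && peak; ++dk) {
              const int kk = k + dk;
              if (kk < 0 || kk >= d3) continue;
              for (int dj = -1; dj <= 1 && peak; ++dj) {
                const int jj = j + dj;
                if (jj < 0 || jj >= d2) continue;
                for (int di = -1; di <= 1; ++di) {
                  const int ii = i + di;
                  if (ii < 0 || ii >= d1) continue;
                  if (di == 0 && dj == 0 && dk == 0 && dsc == 0) continue;
                  if (stack[b2 + ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)] > v) {
                    peak = false;
                    break;
                  }
                }
              }
            }
          }
          if (peak) {
            rows.push_back(i);
            rows.push_back(j);
            rows.push_back(k);
            rows.push_back(sc);
            rows.push_back(v);
          }
        }
  }

  const int np = (int)(rows.size() / 5);
  NumericMatrix out(np, 5);
  for (int p = 0; p < np; ++p)
    for (int c = 0; c < 5; ++c) out(p, c) = rows[5 * p + c];
  return out;
}
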