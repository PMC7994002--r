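#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resize a 3D array to `odim`. order 0 = nearest neighbour (labels),
// order 1 = trilinear. Output voxel centres are mapped back by
// in = (out + 0.5) * (n_in / n_out) - 0.5, clamped to the input grid.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector dim,
                           IntegerVector odim, int order) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector out((R_xlen_t)o1 * o2 * o3);

  for (int k = 0; k < o3; ++k) {
    const double zc = (k + 0.5) * s3 - 0.5;
    for (int j = 0; j < o2; ++j) {
      const double yc = (j + 0.5) * s2 - 0.5;
      for (int i = 0; i < o1; ++i) {
        const double xc = (i + 0.5) * s1 - 0.5;
        const R_xlen_t oidx = i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * k);
        if (order == 0) {
          int ii = (int)std::lround(xc), jj = (int)std::lround(yc),
              kk = (int)std::lround(zc);
          ii = std::min(std::max(ii, 0), d1 - 1);
          jj = std::min(std::max(jj, 0), d2 - 1);
          kk = std::min(std::max(kk, 0), d3 - 1);
          out[oidx] = x[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
        } else {
          double fx = std::min(std::max(xc, 0.0), (double)(d1 - 1));
          double fy = std::min(std::max(yc, 0.0), (double)(d2 - 1));
          double fz = std::min(std::max(zc, 0.0), (double)(d3 - 1));
          const int x0 = std::min((int)fx, d1 - 1), x1 = std::min(x0 + 1, d1 - 1);
          const int y0 = std::min((int)fy, d2 - 1), y1 = std::min(y0 + 1, d2 - 1);
          const int z0 = std::min((int)fz, d3 - 1), z1 = std::min(z0 + 1, d3 - 1);
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double acc = 0.0;
          for (int c = 0; c < 8; ++c) {
            const int xi = (c & 1) ? x1 : x0;
            const int yi = (c & 2) ? y1 : y0;
            const int zi = (c & 4) ? z1 : z0;
            const double w = ((c & 1) ? tx : 1 - tx) * ((c & 2) ? ty : 1 - ty) *
                             ((c & 4) ? tz : 1 - tz);
            acc += w * x[xi + (R_xlen_t)d1 * (yi + (R_xlen_t)d2 * zi)];
          }
          out[oidx] = acc;
        }
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// In-plane rotation of every 2D slice perpendicular to `axis` (1-based) by
// `degrees` about the slice centre. order 0 = nearest (labels), 1 = bilinear.
// Exposed corners are filled with `bg`. cos/sin are snapped so right angles
// map indices exactly.
// [[Rcpp::export]]
NumericVector cpp_rotate_stack(NumericVector x, IntegerVector dim, int axis,
                               double degrees, int order, double bg) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  const double th = degrees * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th);
  if (std::fabs(c) < 1e-12) c = 0.0;
  if (std::fabs(s) < 1e-12) s = 0.0;
  if (std::fabs(c - 1) < 1e-12) c = 1.0;
  if (std::fabs(c + 1) < 1e-12) c = -1.0;
  if (std::fabs(s - 1) < 1e-12) s = 1.0;
  if (std::fabs(s + 1) < 1e-12) s = -1.0;

  // slice axes (0-based): the two axes != axis-1
  const int a0 = axis - 1;
  int u_ax = (a0 == 0) ? 1 : 0;
  int v_ax = (a0 == 2) ? 1 : 2;
  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  const int nu = dims[u_ax], nv = dims[v_ax], ns = dims[a0];
  const double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  const R_xlen_t su = strides[u_ax], sv = strides[v_ax], ss = strides[a0];

  for (int sl = 0; sl < ns; ++sl) {
    const R_xlen_t base = sl * ss;
    for (int v = 0; v < nv; ++v) {
      for (int u = 0; u < nu; ++u) {
        // inverse rotation of the output coordinate
        const double du = u - cu, dv = v - cv;
        const double sx = c * du + s * dv + cu;
        const double sy = -s * du + c * dv + cv;
        double val = bg;
        if (order == 0) {
          const int iu = (int)std::lround(sx), iv = (int)std::lround(sy);
          if (iu >= 0 && iu < nu && iv >= 0 && iv < nv)
            val = x[base + iu * su + iv * sv];
        } else {
          if (sx >= 0 && sx <= nu - 1 && sy >= 0 && sy <= nv - 1) {
            const int x0 = std::min((int)sx, nu - 1), x1 = std::min(x0 + 1, nu - 1);
            const int y0 = std::min((int)sy, nv - 1), y1 = std::min(y0 + 1, nv - 1);
            const double tx = sx - x0, ty = sy - y0;
            val = (1 - tx) * (1 - ty) * x[base + x0 * su + y0 * sv] +
                  tx * (1 - ty) * x[base + x1 * su + y0 * sv] +
                  (1 - tx) * ty * x[base + x0 * su + y1 * sv] +
                  tx * ty * x[base + x1 * su + y1 * sv];
          }
        }
        out[base + u * su + v * sv] = val;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
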