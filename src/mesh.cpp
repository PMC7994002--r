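#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// cube corner offsets (i, j, k)
const int CO[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                      {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
// six-tetrahedron decomposition around the 0-6 diagonal
const int TETS[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                        {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

struct P3 {
  double x, y, z;
};

inline P3 interp(const P3& a, const P3& b, double fa, double fb, double iso) {
  const double t = (iso - fa) / (fb - fa);
  return P3{a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

inline double triArea(const P3& a, const P3& b, const P3& c) {
  const double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  const double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  const double cx = uy * vz - uz * vy;
  const double cy = uz * vx - ux * vz;
  const double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

}  // namespace

// Iso-surface area of a scalar field by marching tetrahedra with linear edge
// interpolation. Vertex coordinates are scaled by `spacing` (physical units),
// so anisotropic voxels are honoured. The caller pads the field so the surface
// closes inside the array.
// [[Rcpp::export]]
double cpp_mt_surface_area(NumericVector f, IntegerVector dim,
                           NumericVector spacing, double iso) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double sp1 = spacing[0], sp2 = spacing[1], sp3 = spacing[2];
  double area = 0.0;

  double vals[8];
  bool ins[8];
  P3 pts[8];

  for (int k = 0; k < d3 - 1; ++k)
    for (int j = 0; j < d2 - 1; ++j)
      for (int i = 0; i < d1 - 1; ++i) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          vals[c] = f[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
          ins[c] = vals[c] > iso;
          nin += ins[c];
          pts[c] = P3{ii * sp1, jj * sp2, kk * sp3};
        }
        if (nin == 0 || nin == 8) continue;

        for (int t = 0; t < 6; ++t) {
          int inIdx[4], outIdx[4], ki = 0, ko = 0;
          for (int c = 0; c < 4; ++c) {
            const int v = TETS[t][c];
            if (ins[v])
              inIdx[ki++] = v;
            else
              outIdx[ko++] = v;
          }
          if (ki == 0 || ki == 4) continue;
          if (ki == 1 || ki == 3) {
            const int apex = (ki == 1) ? inIdx[0] : outIdx[0];
            const int* oth = (ki == 1) ? outIdx : inIdx;
            P3 m0 = interp(pts[apex], pts[oth[0]], vals[apex], vals[oth[0]], iso);
            P3 m1 = interp(pts[apex], pts[oth[1]], vals[apex], vals[oth[1]], iso);
            P3 m2 = interp(pts[apex], pts[oth[2]], vals[apex], vals[oth[2]], iso);
            area += triArea(m0, m1, m2);
          } else {
            P3 m00 = interp(pts[inIdx[0]], pts[outIdx[0]], vals[inIdx[0]], vals[outIdx[0]], iso);
            P3 m01 = interp(pts[inIdx[0]], pts[outIdx[1]], vals[inIdx[0]], vals[outIdx[1]], iso);
            P3 m10 = interp(pts[inIdx[1]], pts[outIdx[0]], vals[inIdx[1]], vals[outIdx[0]], iso);
            P3 m11 = interp(pts[inIdx[1]], pts[outIdx[1]], vals[inIdx[1]], vals[outIdx[1]], iso);
            area += triArea(m00, m01, m11);
            area += triArea(m00, m11, m10);
          }
        }
      }
  return area;
}
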