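#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a 3D column-major array onto a reference grid.
//
// map is the 4x4 homogeneous matrix taking a 0-based reference voxel index
// (i, j, k, 1) to a continuous 0-based voxel index in `data`. interp: 0 =
// nearest neighbour, 1 = trilinear. Voxels that land outside the source
// extent are filled with NA (the out-of-field sentinel).
// [[Rcpp::export(name = ".resampleKernel")]]
NumericVector resampleKernel(NumericVector data, IntegerVector srcDim,
                             NumericMatrix map, IntegerVector refDim,
                             int interp) {
  const int nx = srcDim[0], ny = srcDim[1], nz = srcDim[2];
  const int rx = refDim[0], ry = refDim[1], rz = refDim[2];
  const R_xlen_t nout = (R_xlen_t)rx * ry * rz;
  NumericVector out(nout);
  const double *d = data.begin();
  const double m00 = map(0,0), m01 = map(0,1), m02 = map(0,2), m03 = map(0,3);
  const double m10 = map(1,0), m11 = map(1,1), m12 = map(1,2), m13 = map(1,3);
  const double m20 = map(2,0), m21 = map(2,1), m22 = map(2,2), m23 = map(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < rz; ++k) {
    for (int j = 0; j < ry; ++j) {
      // column start: i varies fastest
      double x0 = m01*j + m02*k + m03;
      double y0 = m11*j + m12*k + m13;
      double z0 = m21*j + m22*k + m23;
      for (int i = 0; i < rx; ++i, ++idx) {
        const double x = m00*i + x0, y = m10*i + y0, z = m20*i + z0;
        if (interp == 0) {
          const long ri = (long)std::lround(x), rj = (long)std::lround(y),
                     rk = (long)std::lround(z);
          if (ri < 0 || ri >= nx || rj < 0 || rj >= ny || rk < 0 || rk >= nz) {
            out[idx] = NA_REAL;
          } else {
            out[idx] = d[ri + (R_xlen_t)nx * (rj + (R_xlen_t)ny * rk)];
          }
        } else {
          const double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
          const long ix = (long)fx, iy = (long)fy, iz = (long)fz;
          if (ix < 0 || ix + 1 >= nx || iy < 0 || iy + 1 >= ny ||
              iz < 0 || iz + 1 >= nz) {
            // allow exact landing on the far face
            if (x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 &&
                z >= 0 && z <= nz - 1) {
              const long ci = (long)std::lround(x), cj = (long)std::lround(y),
                         ck = (long)std::lround(z);
              if (std::fabs(x - ci) < 1e-9 && std::fabs(y - cj) < 1e-9 &&
                  std::fabs(z - ck) < 1e-9) {
                out[idx] = d[ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)];
                continue;
              }
            }
            out[idx] = NA_REAL;
          } else {
            const double wx = x - fx, wy = y - fy, wz = z - fz;
            const R_xlen_t b000 = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            const R_xlen_t b100 = b000 + 1;
            const R_xlen_t b010 = b000 + nx;
            const R_xlen_t b110 = b010 + 1;
            const R_xlen_t b001 = b000 + (R_xlen_t)nx * ny;
            const R_xlen_t b101 = b001 + 1;
            const R_xlen_t b011 = b001 + nx;
            const R_xlen_t b111 = b011 + 1;
            const double c00 = d[b000] * (1 - wx) + d[b100] * wx;
            const double c10 = d[b010] * (1 - wx) + d[b110] * wx;
            const double c01 = d[b001] * (1 - wx) + d[b101] * wx;
            const double c11 = d[b011] * (1 - wx) + d[b111] * wx;
            const double c0 = c00 * (1 - wy) + c10 * wy;
            const double c1 = c01 * (1 - wy) + c11 * wy;
            out[idx] = c0 * (1 - wz) + c1 * wz;
          }
        }
      }
    }
  }
  out.attr("dim") = refDim;
  return out;
}
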