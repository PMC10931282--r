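#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rigid translation of a volume by a fractional number of voxels per axis:
// out(i) = in(i - shift_vox), sampled trilinearly with clamp-to-edge for
// samples outside the grid.
// [[Rcpp::export]]
NumericVector cpp_translate_trilinear(NumericVector vol, IntegerVector dims,
                                      NumericVector shift_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  auto clampi = [](int i, int n) { return std::max(0, std::min(i, n - 1)); };
  auto at = [&](int x, int y, int z) {
    return vol[clampi(x, nx) + (size_t)nx * (clampi(y, ny) + (size_t)ny * clampi(z, nz))];
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double sx = x - shift_vox[0], sy = y - shift_vox[1],
                     sz = z - shift_vox[2];
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                  z0 = (int)std::floor(sz);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const double wz = dz ? fz : 1 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            const double wy = dy ? fy : 1 - fy;
            if (wy == 0.0) continue;
            for (int dx = 0; dx <= 1; ++dx) {
              const double wx = dx ? fx : 1 - fx;
              if (wx == 0.0) continue;
              acc += wx * wy * wz * at(x0 + dx, y0 + dy, z0 + dz);
            }
          }
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
  return out;
}
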