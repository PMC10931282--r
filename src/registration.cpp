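#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double entropy_bits(const std::vector<double> &p, double total) {
  double H = 0.0;
  for (size_t i = 0; i < p.size(); ++i) {
    if (p[i] > 0.0) {
      const double q = p[i] / total;
      H -= q * std::log2(q);
    }
  }
  return H;
}

// Exhaustive integer-voxel sliding search maximizing the mutual information
// between a floating window (the reconstructed MVCT) and same-sized windows of
// the planning CT. Only voxels flagged in `mask` enter the joint histogram.
// start0: 1-based start index of the planned window position; offsets run over
// [-radius, radius] per axis. Intensity bin edges are fixed once: the floating
// image over its masked voxels, the reference over the whole search region.
// Ties are broken by the smallest Euclidean offset, then lexicographically in
// (z, y, x). Returns the best offset, its MI (bits) and the full MI surface.
// [[Rcpp::export]]
List cpp_mi_search(NumericVector mvct, LogicalVector mask, IntegerVector wdim,
                   NumericVector ct, IntegerVector cdim, IntegerVector start0,
                   IntegerVector radius, int bins) {
  const int wx = wdim[0], wy = wdim[1], wz = wdim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  // Masked voxel list with precomputed floating-image bins.
  std::vector<int> lx, ly, lz, bR;
  double rlo = R_PosInf, rhi = R_NegInf;
  for (int k = 0; k < mvct.size(); ++k)
    if (mask[k]) {
      if (mvct[k] < rlo) rlo = mvct[k];
      if (mvct[k] > rhi) rhi = mvct[k];
    }
  if (!R_FINITE(rlo)) stop("no voxels in the registration mask");
  const double rspan = rhi > rlo ? rhi - rlo : 1.0;
  for (int z = 0; z < wz; ++z)
    for (int y = 0; y < wy; ++y)
      for (int x = 0; x < wx; ++x) {
        const size_t k = x + (size_t)wx * (y + (size_t)wy * z);
        if (!mask[k]) continue;
        int b = (int)((mvct[k] - rlo) / rspan * bins);
        if (b >= bins) b = bins - 1;
        if (b < 0) b = 0;
        lx.push_back(x);
        ly.push_back(y);
        lz.push_back(z);
        bR.push_back(b);
      }
  const size_t nm = lx.size();

  // Fixed reference-image range over the search region.
  int lo[3], hi[3];
  const int s0[3] = {start0[0] - 1, start0[1] - 1, start0[2] - 1};
  const int wd[3] = {wx, wy, wz}, cd[3] = {cx, cy, cz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::max(0, s0[a] - radius[a]);
    hi[a] = std::min(cd[a], s0[a] + wd[a] + radius[a]);
  }
  double flo = R_PosInf, fhi = R_NegInf;
  for (int z = lo[2]; z < hi[2]; ++z)
    for (int y = lo[1]; y < hi[1]; ++y)
      for (int x = lo[0]; x < hi[0]; ++x) {
        const double v = ct[x + (size_t)cx * (y + (size_t)cy * z)];
        if (v < flo) flo = v;
        if (v > fhi) fhi = v;
      }
  const double fspan = fhi > flo ? fhi - flo : 1.0;

  const int nx = 2 * radius[0] + 1, ny = 2 * radius[1] + 1,
            nz = 2 * radius[2] + 1;
  NumericVector surface((size_t)nx * ny * nz, NA_REAL);
  std::vector<double> joint((size_t)bins * bins);
  std::vector<double> pr(bins), pf(bins);

  double best_mi = R_NegInf;
  int best_o[3] = {0, 0, 0};
  double best_d2 = R_PosInf;
  bool found = false;

  for (int oz = -radius[2]; oz <= radius[2]; ++oz)
    for (int oy = -radius[1]; oy <= radius[1]; ++oy)
      for (int ox = -radius[0]; ox <= radius[0]; ++ox) {
        const int sx = s0[0] + ox, sy = s0[1] + oy, sz = s0[2] + oz;
        if (sx < 0 || sy < 0 || sz < 0 || sx + wx > cx || sy + wy > cy ||
            sz + wz > cz)
          continue;
        std::fill(joint.begin(), joint.end(), 0.0);
        for (size_t m = 0; m < nm; ++m) {
          const double v =
              ct[(sx + lx[m]) +
                 (size_t)cx * ((sy + ly[m]) + (size_t)cy * (sz + lz[m]))];
          int b = (int)((v - flo) / fspan * bins);
          if (b >= bins) b = bins - 1;
          if (b < 0) b = 0;
          joint[bR[m] * bins + b] += 1.0;
        }
        std::fill(pr.begin(), pr.end(), 0.0);
        std::fill(pf.begin(), pf.end(), 0.0);
        for (int i = 0; i < bins; ++i)
          for (int j = 0; j < bins; ++j) {
            pr[i] += joint[i * bins + j];
            pf[j] += joint[i * bins + j];
          }
        const double total = (double)nm;
        const double mi =
            entropy_bits(pr, total) + entropy_bits(pf, total) -
            entropy_bits(joint, total);
        surface[(ox + radius[0]) +
                (size_t)nx * ((oy + radius[1]) + (size_t)ny * (oz + radius[2]))] =
            mi;
        const double d2 = (double)ox * ox + (double)oy * oy + (double)oz * oz;
        bool better = false;
        if (!found || mi > best_mi + 1e-12) {
          better = true;
        } else if (std::fabs(mi - best_mi) <= 1e-12) {
          if (d2 < best_d2 - 1e-12) {
            better = true;
          } else if (std::fabs(d2 - best_d2) <= 1e-12) {
            const int bo[3] = {best_o[0], best_o[1], best_o[2]};
            if (oz < bo[2] || (oz == bo[2] && (oy < bo[1] ||
                                               (oy == bo[1] && ox < bo[0]))))
              better = true;
          }
        }
        if (better) {
          best_mi = mi;
          best_o[0] = ox;
          best_o[1] = oy;
          best_o[2] = oz;
          best_d2 = d2;
          found = true;
        }
      }
  if (!found) stop("window larger than the search area at every offset");
  return List::create(_["offset"] = IntegerVector::create(best_o[0], best_o[1],
                                                          best_o[2]),
                      _["mi"] = best_mi, _["surface"] = surface,
                      _["surface_dim"] = IntegerVector::create(nx, ny, nz),
                      _["n_masked"] = (double)nm);
}
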