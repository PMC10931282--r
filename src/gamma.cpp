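#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Offset {
  double dx, dy, r2;
};

// Global gamma index of `ev` against `ref` (same pixel grid). For every
// reference pixel at or above low_frac * norm_val, the evaluated map is
// sampled bilinearly on a disk of radius `search_radius` mm at `step` mm
// spacing; gamma^2 = min over samples of (r/dta)^2 + (dD/(tol*norm))^2.
// Offsets are visited in order of increasing distance with early exit once
// the distance term alone exceeds the current best. Samples falling outside
// the map are skipped (boundary pixels use in-map samples only). Pixels below
// the threshold return NA.
// [[Rcpp::export]]
NumericMatrix cpp_gamma(NumericMatrix ref, NumericMatrix ev, double pitch,
                        double dose_tol_frac, double dta, double low_frac,
                        double norm_val, double search_radius, double step,
                        bool local_norm = false) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const double thr = low_frac * norm_val;

  std::vector<Offset> offs;
  const int m = (int)std::floor(search_radius / step);
  for (int i = -m; i <= m; ++i)
    for (int j = -m; j <= m; ++j) {
      Offset o;
      o.dx = i * step;
      o.dy = j * step;
      o.r2 = o.dx * o.dx + o.dy * o.dy;
      if (o.r2 <= search_radius * search_radius + 1e-12) offs.push_back(o);
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.r2 < b.r2; });

  NumericMatrix out(nr, nc);
  const double dta2 = dta * dta;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const double dref = ref(r, c);
      if (dref < thr) {
        out(r, c) = NA_REAL;
        continue;
      }
      const double dd = dose_tol_frac * (local_norm ? dref : norm_val);
      double best = R_PosInf;
      for (size_t k = 0; k < offs.size(); ++k) {
        const double dist2 = offs[k].r2 / dta2;
        if (dist2 >= best) break;  // sorted by distance
        // continuous pixel coordinates (0-based) of the sample
        const double pr = r + offs[k].dy / pitch;
        const double pc = c + offs[k].dx / pitch;
        if (pr < 0 || pr > nr - 1 || pc < 0 || pc > nc - 1) continue;
        const int r0 = (int)std::floor(pr), c0 = (int)std::floor(pc);
        const int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
        const double fr = pr - r0, fc = pc - c0;
        const double val = (1 - fr) * ((1 - fc) * ev(r0, c0) + fc * ev(r0, c1)) +
                           fr * ((1 - fc) * ev(r1, c0) + fc * ev(r1, c1));
        const double dD = (val - dref) / dd;
        const double g2 = dist2 + dD * dD;
        if (g2 < best) best = g2;
      }
      out(r, c) = std::sqrt(best);
    }
  return out;
}
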