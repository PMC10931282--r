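#include <Rcpp.h>
#include "siddon.h"
using namespace Rcpp;

// Smoothed total-variation subgradient of one 2D slice. x is column-major
// (nr rows, nc cols). Terms whose neighbours fall outside the grid are
// dropped, mirroring the valid-index convention of the TV sum itself.
static void tv_gradient_2d(const double *x, int nr, int nc, double eps,
                           double *g) {
  auto at = [&](int i, int j) { return x[i + (size_t)nr * j]; };
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double val = 0.0;
      if (i >= 1 && j >= 1) {
        const double di = at(i, j) - at(i - 1, j);
        const double dj = at(i, j) - at(i, j - 1);
        val += (di + dj) / std::sqrt(eps + di * di + dj * dj);
      }
      if (i + 1 < nr && j >= 1) {
        const double di = at(i + 1, j) - at(i, j);
        const double dj = at(i + 1, j) - at(i + 1, j - 1);
        val -= di / std::sqrt(eps + di * di + dj * dj);
      }
      if (j + 1 < nc && i >= 1) {
        const double dj = at(i, j + 1) - at(i, j);
        const double di = at(i, j + 1) - at(i - 1, j + 1);
        val -= dj / std::sqrt(eps + di * di + dj * dj);
      }
      g[i + (size_t)nr * j] = val;
    }
  }
}

// Smoothed TV subgradient; 2D grids directly, 3D grids slice-by-slice along
// the third (axial) dimension.
// [[Rcpp::export]]
NumericVector cpp_tv_gradient(NumericVector x, IntegerVector dims, double eps) {
  NumericVector g(x.size());
  const int nr = dims[0], nc = dims[1];
  const int nz = dims.size() > 2 ? dims[2] : 1;
  const size_t slice = (size_t)nr * nc;
  for (int z = 0; z < nz; ++z)
    tv_gradient_2d(&x[0] + z * slice, nr, nc, eps, &g[0] + z * slice);
  return g;
}

static double tv_norm_2d(const double *x, int nr, int nc) {
  double s = 0.0;
  for (int j = 1; j < nc; ++j)
    for (int i = 1; i < nr; ++i) {
      const double di = x[i + (size_t)nr * j] - x[(i - 1) + (size_t)nr * j];
      const double dj = x[i + (size_t)nr * j] - x[i + (size_t)nr * (j - 1)];
      s += std::sqrt(di * di + dj * dj);
    }
  return s;
}

struct ViewGeom {
  double src[3], dc[3], u[3], v[3], beam[3];
  double u0, v0, pitch;
  int nr, nc;
};

// Ray-by-ray ART with non-negativity and adaptive-step TV descent.
// projections: list of matrices of line-integral values; sweep order is
// view-major (first angle first), row-major within each view. cadence:
// 0 = TV step after every ray, 1 = after every view, 2 = after every full
// iteration. Returns the volume, the per-iteration trace and the ray-support
// count per voxel.
// [[Rcpp::export]]
List cpp_art_tv(List projections, NumericVector angles, NumericMatrix uv0,
                NumericVector pitches, double SAD, double SID,
                IntegerVector dims, NumericVector voxel, NumericVector origin,
                int n_iter, double lambda, double mu, double eps,
                double stop_tol, int cadence, bool parallel = false) {
  const int nview = projections.size();
  std::vector<ViewGeom> geo(nview);
  std::vector<NumericMatrix> proj(nview);
  for (int w = 0; w < nview; ++w) {
    proj[w] = as<NumericMatrix>(projections[w]);
    gantry_frame(angles[w], SAD, SID, geo[w].src, geo[w].dc, geo[w].u,
                 geo[w].v, geo[w].beam);
    geo[w].u0 = uv0(w, 0);
    geo[w].v0 = uv0(w, 1);
    geo[w].pitch = pitches[w];
    geo[w].nr = proj[w].nrow();
    geo[w].nc = proj[w].ncol();
  }
  double org[3] = {origin[0], origin[1], origin[2]};
  double h[3] = {voxel[0], voxel[1], voxel[2]};
  int n[3] = {dims[0], dims[1], dims[2]};
  const size_t nvox = (size_t)n[0] * n[1] * n[2];

  NumericVector x(nvox);
  IntegerVector support(nvox);
  std::vector<double> xprev(nvox, 0.0), grad(nvox), xsnap(nvox, 0.0);
  std::vector<Crossing> path;

  NumericVector tr_d(n_iter, NA_REAL), tr_tv(n_iter, NA_REAL),
      tr_rel(n_iter, NA_REAL);
  IntegerVector tr_it(n_iter);
  int done = 0;

  auto tv_step = [&](double d) {
    if (d <= 0.0 || mu <= 0.0) return;
    const size_t slice = (size_t)n[0] * n[1];
    for (int z = 0; z < n[2]; ++z)
      tv_gradient_2d(&x[0] + z * slice, n[0], n[1], eps, grad.data() + z * slice);
    double vn = 0.0;
    for (size_t i = 0; i < nvox; ++i) vn += grad[i] * grad[i];
    vn = std::sqrt(vn);
    if (vn <= 0.0) return;
    const double s = mu * d / vn;
    for (size_t i = 0; i < nvox; ++i) {
      x[i] -= s * grad[i];
      if (x[i] < 0.0) x[i] = 0.0;
    }
  };

  // d for the batched cadences is the net L2 norm of the ART-induced change
  // accumulated since the previous TV step (xsnap is refreshed after each TV
  // step, so the TV movement itself is excluded)
  auto batched_tv_step = [&]() {
    double d2 = 0.0;
    for (size_t i = 0; i < nvox; ++i) {
      const double dd = x[i] - xsnap[i];
      d2 += dd * dd;
    }
    tv_step(std::sqrt(d2));
    std::copy(x.begin(), x.end(), xsnap.begin());
  };

  for (int t = 0; t < n_iter; ++t) {
    double d2_iter = 0.0;
    for (int w = 0; w < nview; ++w) {
      double d2_view = 0.0;
      const ViewGeom &g = geo[w];
      double p0[3], p1[3];
      for (int r = 0; r < g.nr; ++r) {
        const double v_mm = g.v0 + r * g.pitch;
        for (int c = 0; c < g.nc; ++c) {
          const double u_mm = g.u0 + c * g.pitch;
          ray_endpoints(u_mm, v_mm, parallel, SAD, SID, g.src, g.dc, g.u, g.v,
                        g.beam, p0, p1);
          siddon_trace(p0, p1, org, h, n, 1.0, path);
          if (path.empty()) continue;
          double wx = 0.0, wnorm2 = 0.0;
          for (size_t k = 0; k < path.size(); ++k) {
            wx += x[path[k].idx] * path[k].len;
            wnorm2 += path[k].len * path[k].len;
            if (t == 0) support[path[k].idx] += 1;
          }
          if (wnorm2 <= 0.0) continue;
          const double alpha = lambda * (proj[w](r, c) - wx) / wnorm2;
          double d2_ray = 0.0;
          for (size_t k = 0; k < path.size(); ++k) {
            const int i = path[k].idx;
            const double before = x[i];
            double after = before + alpha * path[k].len;
            if (after < 0.0) after = 0.0;  // non-negativity projection
            x[i] = after;
            const double delta = after - before;
            d2_ray += delta * delta;
          }
          d2_view += d2_ray;
          if (cadence == 0) tv_step(std::sqrt(d2_ray));
        }
      }
      d2_iter += d2_view;
      if (cadence == 1) batched_tv_step();
    }
    if (cadence == 2) batched_tv_step();

    double xn = 0.0, dn = 0.0;
    for (size_t i = 0; i < nvox; ++i) {
      xn += x[i] * x[i];
      const double dd = x[i] - xprev[i];
      dn += dd * dd;
      xprev[i] = x[i];
    }
    xn = std::sqrt(xn);
    tr_it[t] = t + 1;
    tr_d[t] = std::sqrt(d2_iter);
    tr_rel[t] = xn > 0.0 ? std::sqrt(dn) / xn : 0.0;
    {
      const size_t slice = (size_t)n[0] * n[1];
      double tv = 0.0;
      for (int z = 0; z < n[2]; ++z)
        tv += tv_norm_2d(&x[0] + z * slice, n[0], n[1]);
      tr_tv[t] = tv;
    }
    done = t + 1;
    if (tr_d[t] < stop_tol * std::max(xn, 1e-300)) break;
  }

  return List::create(
      _["x"] = x, _["support"] = support, _["iterations"] = done,
      _["trace_iteration"] = tr_it, _["trace_d"] = tr_d,
      _["trace_rel_change"] = tr_rel, _["trace_tv"] = tr_tv);
}
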