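#include <Rcpp.h>
#include "siddon.h"
using namespace Rcpp;

// Trace one segment through a grid; returns 1-based linear voxel indices and
// intersection lengths (mm). tau_max < 1 truncates the segment (used for
// partial water-equivalent path lengths up to a plane).
// [[Rcpp::export]]
List cpp_trace_segment(NumericVector p0, NumericVector p1, NumericVector origin,
                       NumericVector voxel, IntegerVector dims,
                       double tau_max = 1.0) {
  double a0[3] = {p0[0], p0[1], p0[2]};
  double a1[3] = {p1[0], p1[1], p1[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double h[3] = {voxel[0], voxel[1], voxel[2]};
  int n[3] = {dims[0], dims[1], dims[2]};
  std::vector<Crossing> path;
  siddon_trace(a0, a1, org, h, n, tau_max, path);
  IntegerVector idx(path.size());
  NumericVector len(path.size());
  for (size_t k = 0; k < path.size(); ++k) {
    idx[k] = path[k].idx + 1;
    len[k] = path[k].len;
  }
  return List::create(_["index"] = idx, _["length"] = len);
}

// Ray sums (line integrals of the volume, mm * value units) for every pixel of
// a detector grid at one gantry angle. u0/v0: detector (u, v) mm of pixel
// (1, 1)'s centre; rows advance along v, columns along u. tau_max truncates
// every ray at the same segment fraction (the plane at distance
// d = tau_max * SID from the source, since detector pixels all lie at axial
// depth SID).
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector origin, NumericVector voxel,
                                  double angle, double SAD, double SID,
                                  int nrow, int ncol, double pitch, double u0,
                                  double v0, bool parallel = false,
                                  double tau_max = 1.0) {
  double src[3], dc[3], u[3], v[3], beam[3];
  gantry_frame(angle, SAD, SID, src, dc, u, v, beam);
  double org[3] = {origin[0], origin[1], origin[2]};
  double h[3] = {voxel[0], voxel[1], voxel[2]};
  int n[3] = {dims[0], dims[1], dims[2]};
  NumericMatrix out(nrow, ncol);
  std::vector<Crossing> path;
  double p0[3], p1[3];
  for (int c = 0; c < ncol; ++c) {
    const double u_mm = u0 + c * pitch;
    for (int r = 0; r < nrow; ++r) {
      const double v_mm = v0 + r * pitch;
      ray_endpoints(u_mm, v_mm, parallel, SAD, SID, src, dc, u, v, beam, p0,
                    p1);
      siddon_trace(p0, p1, org, h, n, tau_max, path);
      double s = 0.0;
      for (size_t k = 0; k < path.size(); ++k)
        s += vol[path[k].idx] * path[k].len;
      out(r, c) = s;
    }
  }
  return out;
}
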