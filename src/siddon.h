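#pragma once
#include <vector>
#include <cmath>
#include <algorithm>

// Exact voxel traversal (Siddon-style) of the segment p0 -> p1 (world mm)
// through a regular grid. `origin` is the world position of the corner of
// voxel (0,0,0); `h` the voxel size; `n` the grid dimensions. Crossings are
// emitted as 0-based linear indices ix + nx*(iy + ny*iz) with intersection
// lengths in mm, restricted to the segment fraction [0, tau_max].
struct Crossing {
  int idx;
  double len;
};

inline void siddon_trace(const double p0[3], const double p1[3],
                         const double origin[3], const double h[3],
                         const int n[3], double tau_max,
                         std::vector<Crossing> &out) {
  out.clear();
  double d[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    L2 += d[a] * d[a];
  }
  const double L = std::sqrt(L2);
  if (L <= 0.0) return;
  double t0 = 0.0, t1 = std::min(1.0, tau_max);
  if (t1 <= 0.0) return;
  for (int a = 0; a < 3; ++a) {
    const double lo = origin[a], hi = origin[a] + n[a] * h[a];
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] <= lo || p0[a] >= hi) return;
    } else {
      double ta = (lo - p0[a]) / d[a], tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return;

  int iv[3], step[3];
  double tnext[3], dt[3];
  for (int a = 0; a < 3; ++a) {
    const double pa = p0[a] + (t0 + 1e-12) * d[a];
    int i = (int)std::floor((pa - origin[a]) / h[a]);
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    iv[a] = i;
    if (std::fabs(d[a]) < 1e-12) {
      step[a] = 0;
      tnext[a] = 1e300;
      dt[a] = 1e300;
    } else if (d[a] > 0) {
      step[a] = 1;
      tnext[a] = (origin[a] + (i + 1) * h[a] - p0[a]) / d[a];
      dt[a] = h[a] / d[a];
    } else {
      step[a] = -1;
      tnext[a] = (origin[a] + i * h[a] - p0[a]) / d[a];
      dt[a] = -h[a] / d[a];
    }
  }
  double tcur = t0;
  while (tcur < t1 - 1e-15) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    const double tstop = std::min(tnext[a], t1);
    const double len = (tstop - tcur) * L;
    if (len > 0.0) {
      Crossing c;
      c.idx = iv[0] + n[0] * (iv[1] + n[1] * iv[2]);
      c.len = len;
      out.push_back(c);
    }
    tcur = tstop;
    if (tnext[a] >= t1) break;
    iv[a] += step[a];
    if (iv[a] < 0 || iv[a] >= n[a]) break;
    tnext[a] += dt[a];
  }
}

// Beam-line geometry: isocenter at the world origin; x = patient left,
// y = anterior -> posterior, z = superior -> inferior. At gantry angle 0 the
// source sits on +y and the beam travels along -y. The detector plane is
// perpendicular to the beam axis at distance SID from the source, spanned by
// u (in-plane lateral) and v (= +z).
inline void gantry_frame(double angle_deg, double SAD, double SID,
                         double src[3], double det_center[3], double u[3],
                         double v[3], double beam[3]) {
  const double th = angle_deg * M_PI / 180.0;
  const double s = std::sin(th), c = std::cos(th);
  src[0] = SAD * s;
  src[1] = SAD * c;
  src[2] = 0.0;
  det_center[0] = -(SID - SAD) * s;
  det_center[1] = -(SID - SAD) * c;
  det_center[2] = 0.0;
  u[0] = c;
  u[1] = -s;
  u[2] = 0.0;
  v[0] = 0.0;
  v[1] = 0.0;
  v[2] = 1.0;
  beam[0] = -s;
  beam[1] = -c;
  beam[2] = 0.0;
}

// End points of the ray feeding detector pixel (u_mm, v_mm). Cone beam: the
// ray runs source -> pixel. Parallel beam: the ray is parallel to the beam
// axis through the pixel's lateral position scaled back to the isocenter
// plane (pitch at isocenter = detector pitch * SAD / SID).
inline void ray_endpoints(double u_mm, double v_mm, bool parallel, double SAD,
                          double SID, const double src[3],
                          const double det_center[3], const double u[3],
                          const double v[3], const double beam[3], double p0[3],
                          double p1[3]) {
  if (!parallel) {
    for (int a = 0; a < 3; ++a) {
      p0[a] = src[a];
      p1[a] = det_center[a] + u_mm * u[a] + v_mm * v[a];
    }
  } else {
    const double ui = u_mm * SAD / SID, vi = v_mm * SAD / SID;
    for (int a = 0; a < 3; ++a) {
      const double iso_pt = ui * u[a] + vi * v[a];
      p0[a] = iso_pt - SAD * beam[a];
      p1[a] = iso_pt + (SID - SAD) * beam[a];
    }
  }
}
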