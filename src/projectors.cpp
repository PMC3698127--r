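// Fan-beam (2D) and cone-beam (3D) projectors for a circular trajectory.
//
// Conventions (shared with the R-level geometry code):
//   * rotation is counter-clockwise, angle origin 0 rad;
//   * at view angle theta the source sits at -SAD * omega with
//     omega = (cos theta, sin theta), the flat detector is centred on the
//     source-axis line at +(SDD - SAD) * omega, with in-plane axis
//     e_u = (-sin theta, cos theta) and (3D) row axis e_w = +z;
//   * voxel centres lie at origin + (index + 0.5) * pitch, 0-based indices;
//   * detector pixel centres at u = (d - (D - 1)/2) * det_pitch.
//
// The forward projector is pixel-driven: each source->pixel ray is clipped
// to the volume bounding box and sampled at a step <= pitch/2 with
// bi/trilinear interpolation (midpoint rule).  The back projector is
// voxel-driven: each voxel is mapped through the source onto the detector
// and accumulates the linearly interpolated detector value over all views.
// The pair is deliberately unmatched (it mirrors GPU texture-based
// implementations); an exactly matched pair is available through the dense
// system matrix, whose entries are generated by the very same ray-sampling
// loop as the forward projector.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// Clip parametric ray s + t*d to slab [lo, hi] along one axis.
inline bool clip_axis(double s, double d, double lo, double hi,
                      double &tmin, double &tmax) {
  if (d == 0.0) return s >= lo && s <= hi;
  double t0 = (lo - s) / d, t1 = (hi - s) / d;
  if (t0 > t1) std::swap(t0, t1);
  if (t0 > tmin) tmin = t0;
  if (t1 < tmax) tmax = t1;
  return tmin < tmax;
}

struct Ray2 {
  double sx, sy, dx, dy, tmin, tmax; // dx,dy unit direction
  bool hit;
};

inline Ray2 make_ray2(double sx, double sy, double px, double py,
                      double ox, double oy, int nx, int ny, double pitch) {
  Ray2 r;
  r.sx = sx; r.sy = sy;
  double dx = px - sx, dy = py - sy;
  double len = std::sqrt(dx * dx + dy * dy);
  r.dx = dx / len; r.dy = dy / len;
  r.tmin = 0.0; r.tmax = len;
  r.hit = clip_axis(sx, r.dx, ox, ox + nx * pitch, r.tmin, r.tmax) &&
          clip_axis(sy, r.dy, oy, oy + ny * pitch, r.tmin, r.tmax);
  return r;
}

} // namespace

// [[Rcpp::export(name = ".cpp_forward_fan2d")]]
NumericMatrix cpp_forward_fan2d(NumericMatrix vol, double pitch,
                                double ox, double oy,
                                NumericVector angles,
                                double sad, double sdd,
                                double det_pitch, int det_count) {
  const int nx = vol.nrow(), ny = vol.ncol(), nv = angles.size();
  const double h = pitch / 2.0;
  NumericMatrix out(nv, det_count);
  for (int v = 0; v < nv; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double sx = -sad * ct, sy = -sad * st;
    const double cx = (sdd - sad) * ct, cy = (sdd - sad) * st;
    const double eux = -st, euy = ct;
    for (int d = 0; d < det_count; ++d) {
      const double u = (d - (det_count - 1) / 2.0) * det_pitch;
      Ray2 r = make_ray2(sx, sy, cx + u * eux, cy + u * euy,
                         ox, oy, nx, ny, pitch);
      if (!r.hit) continue;
      const double L = r.tmax - r.tmin;
      if (L <= 0.0) continue;
      int K = (int)std::ceil(L / h);
      if (K < 1) K = 1;
      const double dt = L / K;
      double acc = 0.0;
      for (int k = 1; k <= K; ++k) {
        const double t = r.tmin + (k - 0.5) * dt;
        const double gx = (r.sx + t * r.dx - ox) / pitch - 0.5;
        const double gy = (r.sy + t * r.dy - oy) / pitch - 0.5;
        const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
        const double fx = gx - i0, fy = gy - j0;
        double val = 0.0;
        for (int di = 0; di <= 1; ++di) {
          const int i = i0 + di;
          if (i < 0 || i >= nx) continue;
          const double wx = di ? fx : 1.0 - fx;
          for (int dj = 0; dj <= 1; ++dj) {
            const int j = j0 + dj;
            if (j < 0 || j >= ny) continue;
            const double wy = dj ? fy : 1.0 - fy;
            val += wx * wy * vol(i, j);
          }
        }
        acc += val;
      }
      out(v, d) = acc * dt;
    }
  }
  return out;
}

// Dense system matrix for the fan-beam forward model: entry (ray, voxel)
// holds the accumulated interpolation weight x step length, so that
// A %*% as.vector(vol) reproduces cpp_forward_fan2d exactly.  Ray index
// r = view + n_views * det matches as.vector() of the (views x det) sinogram.
// [[Rcpp::export(name = ".cpp_sysmat_fan2d")]]
NumericMatrix cpp_sysmat_fan2d(int nx, int ny, double pitch,
                               double ox, double oy,
                               NumericVector angles,
                               double sad, double sdd,
                               double det_pitch, int det_count) {
  const int nv = angles.size();
  const double h = pitch / 2.0;
  NumericMatrix A(nv * det_count, nx * ny);
  for (int v = 0; v < nv; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double sx = -sad * ct, sy = -sad * st;
    const double cx = (sdd - sad) * ct, cy = (sdd - sad) * st;
    const double eux = -st, euy = ct;
    for (int d = 0; d < det_count; ++d) {
      const int row = v + nv * d;
      const double u = (d - (det_count - 1) / 2.0) * det_pitch;
      Ray2 r = make_ray2(sx, sy, cx + u * eux, cy + u * euy,
                         ox, oy, nx, ny, pitch);
      if (!r.hit) continue;
      const double L = r.tmax - r.tmin;
      if (L <= 0.0) continue;
      int K = (int)std::ceil(L / h);
      if (K < 1) K = 1;
      const double dt = L / K;
      for (int k = 1; k <= K; ++k) {
        const double t = r.tmin + (k - 0.5) * dt;
        const double gx = (r.sx + t * r.dx - ox) / pitch - 0.5;
        const double gy = (r.sy + t * r.dy - oy) / pitch - 0.5;
        const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
        const double fx = gx - i0, fy = gy - j0;
        for (int di = 0; di <= 1; ++di) {
          const int i = i0 + di;
          if (i < 0 || i >= nx) continue;
          const double wx = di ? fx : 1.0 - fx;
          for (int dj = 0; dj <= 1; ++dj) {
            const int j = j0 + dj;
            if (j < 0 || j >= ny) continue;
            const double wy = dj ? fy : 1.0 - fy;
            A(row, i + nx * j) += wx * wy * dt;
          }
        }
      }
    }
  }
  return A;
}

// Voxel-driven accumulation back projector (unweighted; the adjoint-like
// partner of the pixel-driven forward projector, not its exact transpose).
// [[Rcpp::export(name = ".cpp_back_fan2d")]]
NumericMatrix cpp_back_fan2d(NumericMatrix proj, int nx, int ny,
                             double pitch, double ox, double oy,
                             NumericVector angles,
                             double sad, double sdd, double det_pitch) {
  const int nv = angles.size(), nd = proj.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> ct(nv), st(nv);
  for (int v = 0; v < nv; ++v) { ct[v] = std::cos(angles[v]); st[v] = std::sin(angles[v]); }
  for (int j = 0; j < ny; ++j) {
    const double vy = oy + (j + 0.5) * pitch;
    for (int i = 0; i < nx; ++i) {
      const double vx = ox + (i + 0.5) * pitch;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        const double denom = sad + vx * ct[v] + vy * st[v];
        if (denom <= 1e-9) continue;
        const double u = sdd * (-vx * st[v] + vy * ct[v]) / denom;
        const double di = u / det_pitch + (nd - 1) / 2.0;
        const int d0 = (int)std::floor(di);
        const double f = di - d0;
        if (d0 >= 0 && d0 < nd) acc += (1.0 - f) * proj(v, d0);
        if (d0 + 1 >= 0 && d0 + 1 < nd) acc += f * proj(v, d0 + 1);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Distance-weighted back projector for filtered back-projection; expects
// row-filtered projections expressed on the virtual detector through the
// isocentre (pixel pitch det_pitch * sad / sdd).  Applies the 1/U^2 fan/cone
// weight; the angular step factor is applied at the R level.
// [[Rcpp::export(name = ".cpp_back_fbp2d")]]
NumericMatrix cpp_back_fbp2d(NumericMatrix proj, int nx, int ny,
                             double pitch, double ox, double oy,
                             NumericVector angles,
                             double sad, double det_pitch_virtual) {
  const int nv = angles.size(), nd = proj.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> ct(nv), st(nv);
  for (int v = 0; v < nv; ++v) { ct[v] = std::cos(angles[v]); st[v] = std::sin(angles[v]); }
  for (int j = 0; j < ny; ++j) {
    const double vy = oy + (j + 0.5) * pitch;
    for (int i = 0; i < nx; ++i) {
      const double vx = ox + (i + 0.5) * pitch;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        const double denom = sad + vx * ct[v] + vy * st[v];
        if (denom <= 1e-9) continue;
        const double U = denom / sad;
        const double u = sad * (-vx * st[v] + vy * ct[v]) / denom;
        const double di = u / det_pitch_virtual + (nd - 1) / 2.0;
        const int d0 = (int)std::floor(di);
        const double f = di - d0;
        double q = 0.0;
        if (d0 >= 0 && d0 < nd) q += (1.0 - f) * proj(v, d0);
        if (d0 + 1 >= 0 && d0 + 1 < nd) q += f * proj(v, d0 + 1);
        acc += q / (U * U);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------- cone3d --

// [[Rcpp::export(name = ".cpp_forward_cone3d")]]
NumericVector cpp_forward_cone3d(NumericVector vol, IntegerVector dim,
                                 double pitch,
                                 double ox, double oy, double oz,
                                 NumericVector angles,
                                 double sad, double sdd,
                                 double det_pitch, int det_count,
                                 int det_rows) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nv = angles.size();
  const double h = pitch / 2.0;
  NumericVector out(nv * det_rows * det_count); // (views, rows, det)
  for (int v = 0; v < nv; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double sx = -sad * ct, sy = -sad * st;
    const double cx = (sdd - sad) * ct, cy = (sdd - sad) * st;
    const double eux = -st, euy = ct;
    for (int d = 0; d < det_count; ++d) {
      const double u = (d - (det_count - 1) / 2.0) * det_pitch;
      const double px = cx + u * eux, py = cy + u * euy;
      for (int r = 0; r < det_rows; ++r) {
        const double pz = (r - (det_rows - 1) / 2.0) * det_pitch;
        double dx = px - sx, dy = py - sy, dz = pz;
        const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= len; dy /= len; dz /= len;
        double tmin = 0.0, tmax = len;
        bool hit =
          clip_axis(sx, dx, ox, ox + nx * pitch, tmin, tmax) &&
          clip_axis(sy, dy, oy, oy + ny * pitch, tmin, tmax) &&
          clip_axis(0.0, dz, oz, oz + nz * pitch, tmin, tmax);
        if (!hit) continue;
        const double L = tmax - tmin;
        if (L <= 0.0) continue;
        int K = (int)std::ceil(L / h);
        if (K < 1) K = 1;
        const double dt = L / K;
        double acc = 0.0;
        for (int k = 1; k <= K; ++k) {
          const double t = tmin + (k - 0.5) * dt;
          const double gx = (sx + t * dx - ox) / pitch - 0.5;
          const double gy = (sy + t * dy - oy) / pitch - 0.5;
          const double gz = (t * dz - oz) / pitch - 0.5;
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          double val = 0.0;
          for (int di = 0; di <= 1; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= nx) continue;
            const double wx = di ? fx : 1.0 - fx;
            for (int dj = 0; dj <= 1; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= ny) continue;
              const double wxy = wx * (dj ? fy : 1.0 - fy);
              for (int dk = 0; dk <= 1; ++dk) {
                const int kk = k0 + dk;
                if (kk < 0 || kk >= nz) continue;
                val += wxy * (dk ? fz : 1.0 - fz) *
                       vol[i + nx * (j + ny * kk)];
              }
            }
          }
          acc += val;
        }
        out[v + nv * (r + det_rows * d)] = acc * dt;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nv, det_rows, det_count);
  return out;
}

// [[Rcpp::export(name = ".cpp_sysmat_cone3d")]]
NumericMatrix cpp_sysmat_cone3d(IntegerVector dim, double pitch,
                                double ox, double oy, double oz,
                                NumericVector angles,
                                double sad, double sdd,
                                double det_pitch, int det_count,
                                int det_rows) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nv = angles.size();
  const double h = pitch / 2.0;
  NumericMatrix A(nv * det_rows * det_count, nx * ny * nz);
  for (int v = 0; v < nv; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double sx = -sad * ct, sy = -sad * st;
    const double cx = (sdd - sad) * ct, cy = (sdd - sad) * st;
    const double eux = -st, euy = ct;
    for (int d = 0; d < det_count; ++d) {
      const double u = (d - (det_count - 1) / 2.0) * det_pitch;
      const double px = cx + u * eux, py = cy + u * euy;
      for (int r = 0; r < det_rows; ++r) {
        const int row = v + nv * (r + det_rows * d);
        const double pz = (r - (det_rows - 1) / 2.0) * det_pitch;
        double dx = px - sx, dy = py - sy, dz = pz;
        const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= len; dy /= len; dz /= len;
        double tmin = 0.0, tmax = len;
        bool hit =
          clip_axis(sx, dx, ox, ox + nx * pitch, tmin, tmax) &&
          clip_axis(sy, dy, oy, oy + ny * pitch, tmin, tmax) &&
          clip_axis(0.0, dz, oz, oz + nz * pitch, tmin, tmax);
        if (!hit) continue;
        const double L = tmax - tmin;
        if (L <= 0.0) continue;
        int K = (int)std::ceil(L / h);
        if (K < 1) K = 1;
        const double dt = L / K;
        for (int k = 1; k <= K; ++k) {
          const double t = tmin + (k - 0.5) * dt;
          const double gx = (sx + t * dx - ox) / pitch - 0.5;
          const double gy = (sy + t * dy - oy) / pitch - 0.5;
          const double gz = (t * dz - oz) / pitch - 0.5;
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          for (int di = 0; di <= 1; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= nx) continue;
            const double wx = di ? fx : 1.0 - fx;
            for (int dj = 0; dj <= 1; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= ny) continue;
              const double wxy = wx * (dj ? fy : 1.0 - fy);
              for (int dk = 0; dk <= 1; ++dk) {
                const int kk = k0 + dk;
                if (kk < 0 || kk >= nz) continue;
                A(row, i + nx * (j + ny * kk)) +=
                  wxy * (dk ? fz : 1.0 - fz) * dt;
              }
            }
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export(name = ".cpp_back_cone3d")]]
NumericVector cpp_back_cone3d(NumericVector proj, IntegerVector pdim,
                              IntegerVector dim, double pitch,
                              double ox, double oy, double oz,
                              NumericVector angles,
                              double sad, double sdd, double det_pitch) {
  const int nv = pdim[0], nr = pdim[1], nd = pdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nx * ny * nz);
  std::vector<double> ct(nv), st(nv);
  for (int v = 0; v < nv; ++v) { ct[v] = std::cos(angles[v]); st[v] = std::sin(angles[v]); }
  for (int k = 0; k < nz; ++k) {
    const double vz = oz + (k + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      const double vy = oy + (j + 0.5) * pitch;
      for (int i = 0; i < nx; ++i) {
        const double vx = ox + (i + 0.5) * pitch;
        double acc = 0.0;
        for (int v = 0; v < nv; ++v) {
          const double denom = sad + vx * ct[v] + vy * st[v];
          if (denom <= 1e-9) continue;
          const double u = sdd * (-vx * st[v] + vy * ct[v]) / denom;
          const double w = sdd * vz / denom;
          const double di = u / det_pitch + (nd - 1) / 2.0;
          const double ri = w / det_pitch + (nr - 1) / 2.0;
          const int d0 = (int)std::floor(di), r0 = (int)std::floor(ri);
          const double fd = di - d0, fr = ri - r0;
          for (int dd = 0; dd <= 1; ++dd) {
            const int d = d0 + dd;
            if (d < 0 || d >= nd) continue;
            const double wd = dd ? fd : 1.0 - fd;
            for (int rr = 0; rr <= 1; ++rr) {
              const int r = r0 + rr;
              if (r < 0 || r >= nr) continue;
              acc += wd * (rr ? fr : 1.0 - fr) *
                     proj[v + nv * (r + nr * d)];
            }
          }
        }
        out[i + nx * (j + ny * k)] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// FDK back projector: bilinear detector interpolation on the virtual
// detector, 1/U^2 weighting; angular step applied at the R level.
// [[Rcpp::export(name = ".cpp_back_fdk3d")]]
NumericVector cpp_back_fdk3d(NumericVector proj, IntegerVector pdim,
                             IntegerVector dim, double pitch,
                             double ox, double oy, double oz,
                             NumericVector angles,
                             double sad, double det_pitch_virtual) {
  const int nv = pdim[0], nr = pdim[1], nd = pdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nx * ny * nz);
  std::vector<double> ct(nv), st(nv);
  for (int v = 0; v < nv; ++v) { ct[v] = std::cos(angles[v]); st[v] = std::sin(angles[v]); }
  for (int k = 0; k < nz; ++k) {
    const double vz = oz + (k + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      const double vy = oy + (j + 0.5) * pitch;
      for (int i = 0; i < nx; ++i) {
        const double vx = ox + (i + 0.5) * pitch;
        double acc = 0.0;
        for (int v = 0; v < nv; ++v) {
          const double denom = sad + vx * ct[v] + vy * st[v];
          if (denom <= 1e-9) continue;
          const double U = denom / sad;
          const double u = sad * (-vx * st[v] + vy * ct[v]) / denom;
          const double w = sad * vz / denom;
          const double di = u / det_pitch_virtual + (nd - 1) / 2.0;
          const double ri = w / det_pitch_virtual + (nr - 1) / 2.0;
          const int d0 = (int)std::floor(di), r0 = (int)std::floor(ri);
          const double fd = di - d0, fr = ri - r0;
          double q = 0.0;
          for (int dd = 0; dd <= 1; ++dd) {
            const int d = d0 + dd;
            if (d < 0 || d >= nd) continue;
            const double wd = dd ? fd : 1.0 - fd;
            for (int rr = 0; rr <= 1; ++rr) {
              const int r = r0 + rr;
              if (r < 0 || r >= nr) continue;
              q += wd * (rr ? fr : 1.0 - fr) * proj[v + nv * (r + nr * d)];
            }
          }
          acc += q / (U * U);
        }
        out[i + nx * (j + ny * k)] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
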