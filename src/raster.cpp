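// Phantom rasterization (supersampled partial-volume rule), trilinear
// sampling, radial chord casting, and point-to-polyline distances.
// World coordinates in mm; voxel (0,0,0) center sits at origin_mm.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { c += (int)(x & 1); x >>= 1; } return c;
#endif
}

// Squared distance from q to segment [p0, p1]; also returns parameter t.
static inline double seg_dist2(const double *q, const double *p0,
                               const double *p1, double *t_out) {
  const double vx = p1[0] - p0[0], vy = p1[1] - p0[1], vz = p1[2] - p0[2];
  const double wx = q[0] - p0[0], wy = q[1] - p0[1], wz = q[2] - p0[2];
  const double vv = vx * vx + vy * vy + vz * vz;
  double t = 0.0;
  if (vv > 0.0) {
    t = (wx * vx + wy * vy + wz * vz) / vv;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  const double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  if (t_out) *t_out = t;
  return dx * dx + dy * dy + dz * dz;
}

// Rasterize vessel primitives into a binary mask.
// prims: list of list(points = n x 3 matrix (mm), radius_mm = numeric n).
// A voxel is foreground iff >= 50% of its supersample points fall inside
// any tube. supersample limited to 4 (64 sample points, fits a bitmask).
// [[Rcpp::export]]
LogicalVector cpp_rasterize(List prims, IntegerVector dim, double voxel_mm,
                            NumericVector origin_mm, int supersample) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int ss = supersample;
  if (ss < 1 || ss > 4) stop("supersample must be in 1..4");
  const int S3 = ss * ss * ss;
  const uint64_t FULL = (S3 == 64) ? ~(uint64_t)0 : (((uint64_t)1 << S3) - 1);

  std::vector<uint64_t> bits(n, 0);
  // supersample offsets (mm), relative to voxel center
  std::vector<double> offx(S3), offy(S3), offz(S3);
  {
    int k = 0;
    for (int c = 0; c < ss; ++c)
      for (int b = 0; b < ss; ++b)
        for (int a = 0; a < ss; ++a, ++k) {
          offx[k] = ((a + 0.5) / ss - 0.5) * voxel_mm;
          offy[k] = ((b + 0.5) / ss - 0.5) * voxel_mm;
          offz[k] = ((c + 0.5) / ss - 0.5) * voxel_mm;
        }
  }
  const double ox = origin_mm[0], oy = origin_mm[1], oz = origin_mm[2];
  const double half_diag = 0.5 * std::sqrt(3.0) * voxel_mm;

  const int np = prims.size();
  for (int ip = 0; ip < np; ++ip) {
    List pr = prims[ip];
    NumericMatrix P = pr["points"];
    NumericVector R = pr["radius_mm"];
    const int m = P.nrow();
    for (int s = 0; s + 1 < m; ++s) {
      double p0[3] = { P(s, 0), P(s, 1), P(s, 2) };
      double p1[3] = { P(s + 1, 0), P(s + 1, 1), P(s + 1, 2) };
      const double r0 = R[s], r1 = R[s + 1];
      const double rmax = std::max(r0, r1);
      // voxel-index bounding box (inflated)
      const double pad = rmax + voxel_mm;
      int x0 = (int)std::floor((std::min(p0[0], p1[0]) - pad - ox) / voxel_mm);
      int x1 = (int)std::ceil((std::max(p0[0], p1[0]) + pad - ox) / voxel_mm);
      int y0 = (int)std::floor((std::min(p0[1], p1[1]) - pad - oy) / voxel_mm);
      int y1 = (int)std::ceil((std::max(p0[1], p1[1]) + pad - oy) / voxel_mm);
      int z0 = (int)std::floor((std::min(p0[2], p1[2]) - pad - oz) / voxel_mm);
      int z1 = (int)std::ceil((std::max(p0[2], p1[2]) + pad - oz) / voxel_mm);
      if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
      if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1;
      if (z1 >= nz) z1 = nz - 1;
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            const R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (bits[i] == FULL) continue;
            double cq[3] = { ox + x * voxel_mm, oy + y * voxel_mm,
                             oz + z * voxel_mm };
            double t;
            const double d2c = seg_dist2(cq, p0, p1, &t);
            const double rc = r0 + t * (r1 - r0);
            const double dc = std::sqrt(d2c);
            if (dc > rc + half_diag) continue;            // fully outside
            if (dc + half_diag <= rc) { bits[i] = FULL; continue; }  // inside
            for (int k = 0; k < S3; ++k) {
              const uint64_t bit = (uint64_t)1 << k;
              if (bits[i] & bit) continue;
              double q[3] = { cq[0] + offx[k], cq[1] + offy[k],
                              cq[2] + offz[k] };
              const double d2 = seg_dist2(q, p0, p1, &t);
              const double r = r0 + t * (r1 - r0);
              if (d2 <= r * r) bits[i] |= bit;
            }
          }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (2 * popcount64(bits[i]) >= S3);
  return out;
}

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double fx, double fy, double fz) {
  // fx, fy, fz in voxel units (0 at center of voxel 0); outside -> 0
  const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
            z0 = (int)std::floor(fz);
  const double ax = fx - x0, ay = fy - y0, az = fz - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        const int x = x0 + dx, y = y0 + dy, z = z0 + dz;
        const double w = (dx ? ax : 1.0 - ax) * (dy ? ay : 1.0 - ay) *
                         (dz ? az : 1.0 - az);
        if (w == 0.0) continue;
        double val = 0.0;
        if (x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz)
          val = v[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        acc += w * val;
      }
  return acc;
}

// Trilinear sampling of a volume at world points (mm).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            double voxel_mm, NumericVector origin_mm,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = pts.nrow();
  NumericVector out(no_init(m));
  const double *v = vol.begin();
  for (int i = 0; i < m; ++i) {
    const double fx = (pts(i, 0) - origin_mm[0]) / voxel_mm;
    const double fy = (pts(i, 1) - origin_mm[1]) / voxel_mm;
    const double fz = (pts(i, 2) - origin_mm[2]) / voxel_mm;
    out[i] = trilinear(v, nx, ny, nz, fx, fy, fz);
  }
  return out;
}

// Full chord lengths (mm) through a binary mask (given as numeric 0/1),
// cast in the plane orthogonal to `tangent` at `point_mm`. n_rays ray-pairs
// uniformly spaced over [0, pi). Boundary at the trilinear 0.5 level.
// Returns NA for rays that never exit within max_mm.
// [[Rcpp::export]]
NumericVector cpp_radial_chords(NumericVector mask, IntegerVector dim,
                                double voxel_mm, NumericVector origin_mm,
                                NumericVector point_mm, NumericVector tangent,
                                int n_rays, double step_mm, double max_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = mask.begin();
  // orthonormal frame (u, w) perpendicular to tangent
  double t[3] = { tangent[0], tangent[1], tangent[2] };
  const double tn = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
  if (tn == 0.0) stop("zero tangent");
  for (int i = 0; i < 3; ++i) t[i] /= tn;
  double a[3] = { 1.0, 0.0, 0.0 };
  if (std::fabs(t[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
  double u[3] = { t[1] * a[2] - t[2] * a[1], t[2] * a[0] - t[0] * a[2],
                  t[0] * a[1] - t[1] * a[0] };
  const double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= un;
  double w[3] = { t[1] * u[2] - t[2] * u[1], t[2] * u[0] - t[0] * u[2],
                  t[0] * u[1] - t[1] * u[0] };

  NumericVector out(no_init(n_rays));
  const int nstep = (int)std::ceil(max_mm / step_mm);
  for (int k = 0; k < n_rays; ++k) {
    const double th = M_PI * k / n_rays;
    const double dx = std::cos(th) * u[0] + std::sin(th) * w[0];
    const double dy = std::cos(th) * u[1] + std::sin(th) * w[1];
    const double dz = std::cos(th) * u[2] + std::sin(th) * w[2];
    double half[2];
    bool ok = true;
    for (int sgn = 0; sgn < 2; ++sgn) {
      const double sg = sgn ? -1.0 : 1.0;
      double prev = trilinear(v, nx, ny, nz,
                              (point_mm[0] - origin_mm[0]) / voxel_mm,
                              (point_mm[1] - origin_mm[1]) / voxel_mm,
                              (point_mm[2] - origin_mm[2]) / voxel_mm);
      double hit = -1.0;
      for (int s = 1; s <= nstep; ++s) {
        const double dmm = s * step_mm;
        const double fx = (point_mm[0] + sg * dmm * dx - origin_mm[0]) / voxel_mm;
        const double fy = (point_mm[1] + sg * dmm * dy - origin_mm[1]) / voxel_mm;
        const double fz = (point_mm[2] + sg * dmm * dz - origin_mm[2]) / voxel_mm;
        const double val = trilinear(v, nx, ny, nz, fx, fy, fz);
        if (val < 0.5) {
          const double frac = (prev - 0.5) / (prev - val);
          hit = (s - 1) * step_mm + frac * step_mm;
          break;
        }
        prev = val;
      }
      if (hit < 0.0) { ok = false; break; }
      half[sgn] = hit;
    }
    out[k] = ok ? (half[0] + half[1]) : NA_REAL;
  }
  return out;
}

// For each row of A (points), distance to the polyline B (consecutive rows
// are segments; a single row is a point).
// [[Rcpp::export]]
NumericVector cpp_points_polyline_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(no_init(na));
  for (int i = 0; i < na; ++i) {
    double q[3] = { A(i, 0), A(i, 1), A(i, 2) };
    double best = R_PosInf;
    if (nb == 1) {
      const double dx = q[0] - B(0, 0), dy = q[1] - B(0, 1),
                   dz = q[2] - B(0, 2);
      best = dx * dx + dy * dy + dz * dz;
    } else {
      for (int s = 0; s + 1 < nb; ++s) {
        double p0[3] = { B(s, 0), B(s, 1), B(s, 2) };
        double p1[3] = { B(s + 1, 0), B(s + 1, 1), B(s + 1, 2) };
        const double d2 = seg_dist2(q, p0, p1, nullptr);
        if (d2 < best) best = d2;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
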