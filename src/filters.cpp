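// Separable 3D filtering, symmetric 3x3 eigenvalues, Frangi combination,
// hysteresis thresholding and connected components for HU volumes.
// Volumes are R arrays dim = c(nx, ny, nz), column-major: x fastest.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Correlate one axis of a 3D volume with a centered kernel (odd length),
// symmetric (mirror) boundary handling.
// [[Rcpp::export]]
NumericVector cpp_conv3_axis(NumericVector vol, IntegerVector dim,
                             NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size(), r = (klen - 1) / 2;
  if (klen % 2 == 0) stop("kernel length must be odd");
  NumericVector out(no_init(vol.size()));
  const double *v = vol.begin(), *k = kernel.begin();
  double *o = out.begin();

  int n;          // length along filtered axis
  R_xlen_t stride;
  int n1, n2;     // the two remaining dims
  R_xlen_t s1, s2;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  if (axis == 0)      { n = nx; stride = sx; n1 = ny; s1 = sy; n2 = nz; s2 = sz; }
  else if (axis == 1) { n = ny; stride = sy; n1 = nx; s1 = sx; n2 = nz; s2 = sz; }
  else                { n = nz; stride = sz; n1 = nx; s1 = sx; n2 = ny; s2 = sy; }

  std::vector<double> buf(n + 2 * r);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) buf[r + i] = v[base + i * stride];
      for (int i = 0; i < r; ++i) {
        buf[r - 1 - i] = v[base + (R_xlen_t)reflect_idx(-1 - i, n) * stride];
        buf[r + n + i] = v[base + (R_xlen_t)reflect_idx(n + i, n) * stride];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *b = &buf[i];
        for (int t = 0; t < klen; ++t) acc += b[t] * k[t];
        o[base + i * stride] = acc;
      }
    }
  }
  return out;
}

// Eigenvalues of the voxelwise symmetric Hessian, sorted |l1| <= |l2| <= |l3|.
// Analytic symmetric 3x3 solver (trigonometric form).
// [[Rcpp::export]]
List cpp_eig3_sorted(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                     NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector L1(no_init(n)), L2(no_init(n)), L3(no_init(n));
  const double twopi3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = hxx[i], b = hyy[i], c = hzz[i];
    const double d = hxy[i], e = hxz[i], f = hyz[i];
    double l[3];
    const double p1 = d * d + e * e + f * f;
    if (p1 == 0.0) {
      l[0] = a; l[1] = b; l[2] = c;
    } else {
      const double q = (a + b + c) / 3.0;
      const double p2 = (a - q) * (a - q) + (b - q) * (b - q) +
                        (c - q) * (c - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // B = (A - qI) / p; r = det(B) / 2
      const double ba = (a - q) / p, bb = (b - q) / p, bc = (c - q) / p;
      const double bd = d / p, be = e / p, bf = f / p;
      double detB = ba * (bb * bc - bf * bf) - bd * (bd * bc - bf * be) +
                    be * (bd * bf - bb * be);
      double rr = detB / 2.0;
      if (rr < -1.0) rr = -1.0;
      if (rr > 1.0) rr = 1.0;
      const double phi = std::acos(rr) / 3.0;
      l[0] = q + 2.0 * p * std::cos(phi);
      l[2] = q + 2.0 * p * std::cos(phi + twopi3);
      l[1] = 3.0 * q - l[0] - l[2];
    }
    // sort ascending by absolute value
    double al0 = std::fabs(l[0]), al1 = std::fabs(l[1]), al2 = std::fabs(l[2]);
    if (al0 > al1) { std::swap(l[0], l[1]); std::swap(al0, al1); }
    if (al1 > al2) { std::swap(l[1], l[2]); std::swap(al1, al2); }
    if (al0 > al1) { std::swap(l[0], l[1]); std::swap(al0, al1); }
    L1[i] = l[0]; L2[i] = l[1]; L3[i] = l[2];
  }
  return List::create(_["l1"] = L1, _["l2"] = L2, _["l3"] = L3);
}

// Frangi tubularity from sorted eigenvalues.
// bright = TRUE enhances bright-on-dark tubes (requires l2, l3 < 0).
// [[Rcpp::export]]
NumericVector cpp_frangi_combine(NumericVector l1, NumericVector l2,
                                 NumericVector l3, double alpha, double beta,
                                 double c, bool bright) {
  const R_xlen_t n = l1.size();
  NumericVector out(n);  // zero-initialized
  const double a2 = 2.0 * alpha * alpha;
  const double b2 = 2.0 * beta * beta;
  const double c2 = 2.0 * c * c;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double e1 = l1[i], e2 = l2[i], e3 = l3[i];
    if (bright) { if (e2 > 0.0 || e3 > 0.0) continue; }
    else        { if (e2 < 0.0 || e3 < 0.0) continue; }
    const double ae2 = std::fabs(e2), ae3 = std::fabs(e3);
    if (ae3 == 0.0) continue;
    const double ra = ae2 / ae3;
    const double rb = std::fabs(e1) / std::sqrt(ae2 * ae3);
    const double s2 = e1 * e1 + e2 * e2 + e3 * e3;
    double v = (1.0 - std::exp(-(ra * ra) / a2)) *
               std::exp(-(rb * rb) / b2);
    if (c2 > 0.0) v *= (1.0 - std::exp(-s2 / c2));
    out[i] = v;
  }
  return out;
}

static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
  {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},
  {-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},{-1,-1,1},
  {0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};
static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

// Hysteresis thresholding: seeds at v >= hi, grown over v >= lo, 26-connected.
// [[Rcpp::export]]
LogicalVector cpp_hysteresis(NumericVector v, IntegerVector dim, double lo,
                             double hi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = v.size();
  std::vector<unsigned char> keep(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (v[i] >= hi) { keep[i] = 1; stack.push_back(i); }
  while (!stack.empty()) {
    const R_xlen_t i = stack.back(); stack.pop_back();
    const int x = (int)(i % nx);
    const int y = (int)((i / nx) % ny);
    const int z = (int)(i / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 26; ++t) {
      const int xx = x + OFF26[t][0], yy = y + OFF26[t][1], zz = z + OFF26[t][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!keep[j] && v[j] >= lo) { keep[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (keep[i] != 0);
  return out;
}

// Connected-component labeling of a binary mask (connectivity 6 or 26).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n);  // 0 = background
  const int no = (connectivity == 6) ? 6 : 26;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t i = stack.back(); stack.pop_back();
      const int x = (int)(i % nx);
      const int y = (int)((i / nx) % ny);
      const int z = (int)(i / ((R_xlen_t)nx * ny));
      for (int t = 0; t < no; ++t) {
        const int *d = (connectivity == 6) ? OFF6[t] : OFF26[t];
        const int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  return lab;
}
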