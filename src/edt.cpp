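// 3D binary-volume primitives: exact squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm), connected-component
// labelling, border-connected hole filling, and maximal-inscribed-sphere
// local thickness evaluated on the half-voxel grid.
//
// Conventions (shared with the R layer):
//  - arrays are column-major, index = i + nx*(j + ny*k);
//  - distances are in grid units (voxel edges = 1);
//  - local thickness works on the doubled grid (half-voxel points at integer
//    coordinates), where all its distances are integer-exact; see the
//    semantics block further down.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double DT_INF = 1e18;

// 1D squared-distance transform of a sampled function f (length n).
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared EDT over a 3D grid to the TRUE voxels of `sites`.
static void sq_edt_3d(const std::vector<char>& sites, const int nx,
                      const int ny, const int nz, std::vector<double>& out) {
  const size_t n = (size_t)nx * ny * nz;
  out.assign(n, DT_INF);
  for (size_t t = 0; t < n; ++t)
    if (sites[t]) out[t] = 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (size_t)nx * j];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) out[base + (size_t)nx * j] = d[j];
    }
  // pass along z
  const size_t stride = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
    }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector sites, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> s(n);
  bool any = false;
  for (size_t t = 0; t < n; ++t) {
    s[t] = sites[t] == TRUE;
    any = any || s[t];
  }
  NumericVector res(n);
  if (!any) {
    std::fill(res.begin(), res.end(), R_PosInf);
    return res;
  }
  std::vector<double> out;
  sq_edt_3d(s, nx, ny, nz, out);
  for (size_t t = 0; t < n; ++t) res[t] = out[t];
  return res;
}

// neighbour offsets for 6- or 26-connectivity
static int neighbour_offsets(int connectivity, int off[26][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off[m][0] = dx; off[m][1] = dy; off[m][2] = dz;
        ++m;
      }
  return m;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  int off[26][3];
  const int m = neighbour_offsets(connectivity, off);

  IntegerVector labels(n, 0);
  std::vector<int64_t> stack;
  int next = 0;
  for (size_t start = 0; start < n; ++start) {
    if (mask[start] != TRUE || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.clear();
    stack.push_back((int64_t)start);
    while (!stack.empty()) {
      int64_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx;
      int j = (cur / nx) % ny;
      int k = cur / ((int64_t)nx * ny);
      for (int t = 0; t < m; ++t) {
        int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int64_t idx = ii + (int64_t)nx * (jj + (int64_t)ny * kk);
        if (mask[idx] == TRUE && labels[idx] == 0) {
          labels[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}

// Fill internal cavities: background connected (6-connectivity) to the grid
// border stays background, everything else becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int64_t> stack;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && j != 0 && k != 0 && i != nx - 1 && j != ny - 1 &&
            k != nz - 1)
          continue;
        int64_t idx = i + (int64_t)nx * (j + (int64_t)ny * k);
        if (mask[idx] != TRUE && !outside[idx]) {
          outside[idx] = 1;
          stack.push_back(idx);
        }
      }
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  while (!stack.empty()) {
    int64_t cur = stack.back();
    stack.pop_back();
    int i = cur % nx;
    int j = (cur / nx) % ny;
    int k = cur / ((int64_t)nx * ny);
    for (int t = 0; t < 6; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int64_t idx = ii + (int64_t)nx * (jj + (int64_t)ny * kk);
      if (mask[idx] != TRUE && !outside[idx]) {
        outside[idx] = 1;
        stack.push_back(idx);
      }
    }
  }
  LogicalVector res(n);
  for (size_t t = 0; t < n; ++t) res[t] = (mask[t] == TRUE) || !outside[t];
  return res;
}

// Local thickness semantics
// -------------------------
// thickness(x) is the diameter of the largest sphere that stays inside the
// structure and covers (intersects the cube of) voxel x, maximized over
// sphere centres on the half-voxel grid:
//
//   boundary samples = half-grid points where at least half of the adjacent
//                      in-bounds voxels are background (the discrete
//                      0.5-isosurface of the binary field; out-of-grid voxels
//                      count as continuation of the volume, not background)
//   radius(p)        = exact Euclidean distance from p to the samples
//   x covered        iff the sphere intersects voxel x's cube
//   thickness(x)     = 2 * max{ radius(p) : p covers x }
//
// A `domain` mask restricts where spheres may be centred (half-grid points
// with a majority of adjacent voxels in the domain) and which voxels receive
// values. With domain == structure this reduces exactly to the plain
// local-thickness transform: every non-boundary half-grid point is then a
// valid centre. The joint-space pipeline uses structure = all non-bone
// voxels and domain = the joint-space mask, so that spheres are bounded by
// bone only and the artificial lateral cut of the mask does not pinch them.
//
// In doubled coordinates (half-grid points at integers, voxel centres at odd
// triples) radius^2 is the integer squared EDT to the samples, and the
// coverage test with per-axis clamped offsets u_i = max(0, |2i+1 - a_i| - 1)
// is sum u_i^2 <= D2 -- all integer-exact. Slabs of any integer thickness t
// measure exactly t voxels (for even t the optimal centre is a half-grid
// mid-plane point); a one-voxel gap measures exactly one voxel.

// strictly more than half of the adjacent in-bounds voxels are foreground?
static inline bool majority_inside(const LogicalVector& mask, int nx, int ny,
                                   int nz, int a, int b, int c) {
  int ilo = std::max(0, (a % 2) ? (a - 1) / 2 : a / 2 - 1);
  int ihi = std::min(nx - 1, a / 2);
  int jlo = std::max(0, (b % 2) ? (b - 1) / 2 : b / 2 - 1);
  int jhi = std::min(ny - 1, b / 2);
  int klo = std::max(0, (c % 2) ? (c - 1) / 2 : c / 2 - 1);
  int khi = std::min(nz - 1, c / 2);
  int fg = 0, total = 0;
  for (int k = klo; k <= khi; ++k)
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i) {
        ++total;
        if (mask[i + (size_t)nx * (j + (size_t)ny * k)] == TRUE) ++fg;
      }
  return 2 * fg > total;
}

// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector structure_mask,
                                  LogicalVector domain, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int dx = 2 * nx + 1, dy = 2 * ny + 1, dz = 2 * nz + 1;
  const size_t nd = (size_t)dx * dy * dz;
  const size_t n = (size_t)nx * ny * nz;

  bool any_bg = false;
  for (size_t t = 0; t < n && !any_bg; ++t) any_bg = structure_mask[t] != TRUE;
  if (!any_bg) stop("mask has no background voxels");

  // sites = boundary samples of the structure
  std::vector<char> sites(nd);
  for (int c = 0; c < dz; ++c)
    for (int b = 0; b < dy; ++b)
      for (int a = 0; a < dx; ++a)
        sites[a + (size_t)dx * (b + (size_t)dy * c)] =
            majority_inside(structure_mask, nx, ny, nz, a, b, c) ? 0 : 1;

  std::vector<double> d2;
  sq_edt_3d(sites, dx, dy, dz, d2);

  // centres: majority-in-domain points with positive radius, sorted by
  // decreasing squared radius
  struct Centre { int d2; int a, b, c; };
  std::vector<Centre> centres;
  for (int c = 0; c < dz; ++c)
    for (int b = 0; b < dy; ++b)
      for (int a = 0; a < dx; ++a) {
        double v = d2[a + (size_t)dx * (b + (size_t)dy * c)];
        if (v > 0.5 && majority_inside(domain, nx, ny, nz, a, b, c)) {
          Centre ct;
          ct.d2 = (int)std::llround(v);
          ct.a = a; ct.b = b; ct.c = c;
          centres.push_back(ct);
        }
      }
  std::sort(centres.begin(), centres.end(),
            [](const Centre& p, const Centre& q) { return p.d2 > q.d2; });

  std::vector<int> best(n, 0);
  for (const Centre& ct : centres) {
    const int D2 = ct.d2;
    const double rd = std::sqrt((double)D2) + 1.0;
    int klo = std::max(0, (int)std::ceil((ct.c - rd - 1.0) / 2.0));
    int khi = std::min(nz - 1, (int)std::floor((ct.c + rd - 1.0) / 2.0));
    for (int k = klo; k <= khi; ++k) {
      int uz = std::max(0, std::abs(2 * k + 1 - ct.c) - 1);
      int rem_z = D2 - uz * uz;
      if (rem_z < 0) continue;
      double ry = std::sqrt((double)rem_z) + 1.0;
      int jlo = std::max(0, (int)std::ceil((ct.b - ry - 1.0) / 2.0));
      int jhi = std::min(ny - 1, (int)std::floor((ct.b + ry - 1.0) / 2.0));
      for (int j = jlo; j <= jhi; ++j) {
        int uy = std::max(0, std::abs(2 * j + 1 - ct.b) - 1);
        int rem_y = rem_z - uy * uy;
        if (rem_y < 0) continue;
        double rx = std::sqrt((double)rem_y) + 1.0;
        int ilo = std::max(0, (int)std::ceil((ct.a - rx - 1.0) / 2.0));
        int ihi = std::min(nx - 1, (int)std::floor((ct.a + rx - 1.0) / 2.0));
        size_t base = (size_t)nx * (j + (size_t)ny * k);
        for (int i = ilo; i <= ihi; ++i) {
          if (domain[base + i] != TRUE) continue;
          int ux = std::max(0, std::abs(2 * i + 1 - ct.a) - 1);
          if (ux * ux + uy * uy + uz * uz > D2) continue;
          if (best[base + i] < D2) best[base + i] = D2;
        }
      }
    }
  }
  NumericVector res(n, 0.0);
  for (size_t t = 0; t < n; ++t)
    if (domain[t] == TRUE)
      res[t] = best[t] > 0 ? std::sqrt((double)best[t]) : 0.0;
  return res;
}

// Brute-force oracle for the same semantics: boundary samples and candidate
// centres are enumerated over the entire doubled grid, radii by direct
// minimum-distance search over all samples, coverage by direct enumeration
// over all centres. No distance transform, no sphere painting; shares only
// the majority_inside definition with the fast path.
// [[Rcpp::export]]
NumericVector cpp_local_thickness_brute(LogicalVector structure_mask,
                                        LogicalVector domain,
                                        IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;

  bool any_bg = false;
  for (size_t t = 0; t < n && !any_bg; ++t) any_bg = structure_mask[t] != TRUE;
  if (!any_bg) stop("mask has no background voxels");

  std::vector<int> site_a, site_b, site_c;
  std::vector<int> cen_a, cen_b, cen_c;
  for (int c = 0; c <= 2 * nz; ++c)
    for (int b = 0; b <= 2 * ny; ++b)
      for (int a = 0; a <= 2 * nx; ++a) {
        if (!majority_inside(structure_mask, nx, ny, nz, a, b, c)) {
          site_a.push_back(a); site_b.push_back(b); site_c.push_back(c);
        } else if (majority_inside(domain, nx, ny, nz, a, b, c)) {
          cen_a.push_back(a); cen_b.push_back(b); cen_c.push_back(c);
        }
      }
  NumericVector res(n, 0.0);
  if (cen_a.empty()) return res;

  const size_t ns = site_a.size(), nc = cen_a.size();
  std::vector<int> rad2(nc);
  for (size_t p = 0; p < nc; ++p) {
    int bestd = INT32_MAX;
    for (size_t t = 0; t < ns; ++t) {
      int da = cen_a[p] - site_a[t];
      int db = cen_b[p] - site_b[t];
      int dc = cen_c[p] - site_c[t];
      int dd = da * da + db * db + dc * dc;
      if (dd < bestd) bestd = dd;
    }
    rad2[p] = bestd;
  }

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        if (domain[idx] != TRUE) continue;
        int xa = 2 * i + 1, xb = 2 * j + 1, xc = 2 * k + 1;
        int best = 0;
        for (size_t p = 0; p < nc; ++p) {
          if (rad2[p] <= best) continue;
          int ua = std::max(0, std::abs(xa - cen_a[p]) - 1);
          int ub = std::max(0, std::abs(xb - cen_b[p]) - 1);
          int uc = std::max(0, std::abs(xc - cen_c[p]) - 1);
          if (ua * ua + ub * ub + uc * uc <= rad2[p]) best = rad2[p];
        }
        res[idx] = std::sqrt((double)best);
      }
  return res;
}
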