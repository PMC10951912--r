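#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays, column-major, dim = (nx, ny, nz).
// Linear index: i + nx*(j + ny*k).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s; f holds squared distances, overwritten in place via buffers.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sq = f[q] + s2 * q * q;
    double inter;
    while (true) {
      int p = v[kk];
      inter = (sq - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (inter <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = inter;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    double dq = s * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// Squared EDT: distance from every voxel to the nearest voxel where
// mask == 0 (background). spacing = per-axis physical size.
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double BIG = 1e15; // finite cap keeps parabola arithmetic well-defined
  NumericVector g((R_xlen_t)nx * ny * nz);

  std::vector<double> f, d;
  // pass along x: two-sweep scan gives squared distance to nearest
  // background voxel within the row
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double run = BIG;
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        run = mask[p] ? (run > BIG - 1 ? BIG : run + spacing[0]) : 0.0;
        g[p] = run;
      }
      run = BIG;
      for (int i = nx - 1; i >= 0; --i) {
        int p = idx3(i, j, k, nx, ny);
        run = mask[p] ? (run > BIG - 1 ? BIG : run + spacing[0]) : 0.0;
        if (run < g[p]) g[p] = run;
        g[p] = g[p] > BIG - 1 ? BIG : g[p] * g[p];
      }
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }
  return g; // squared distances
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, reflecting boundaries; sigma in voxels.
static void blur_axis(NumericVector& img, int nx, int ny, int nz, int axis,
                      double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double ssum = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    ssum += ker[t + r];
  }
  for (auto& v : ker) v /= ssum;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(n), out(n);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < n; ++t) {
        int i, j, k;
        if (axis == 0)      { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else                { i = a; j = b; k = t; }
        line[t] = img[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int u = -r; u <= r; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;          // reflect
          if (p >= n) p = 2 * n - p - 1;
          acc += ker[u + r] * line[p];
        }
        out[t] = acc;
      }
      for (int t = 0; t < n; ++t) {
        int i, j, k;
        if (axis == 0)      { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else                { i = a; j = b; k = t; }
        img[idx3(i, j, k, nx, ny)] = out[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector img, IntegerVector dim,
                             NumericVector sigma_vox) {
  NumericVector out = clone(img);
  blur_axis(out, dim[0], dim[1], dim[2], 0, sigma_vox[0]);
  blur_axis(out, dim[0], dim[1], dim[2], 1, sigma_vox[1]);
  blur_axis(out, dim[0], dim[1], dim[2], 2, sigma_vox[2]);
  return out;
}

// ---------------------------------------------------------------------------
// Running max (or min) along one axis with half-window h (voxels); the
// building block for grayscale erosion/dilation with line/box elements.
// [[Rcpp::export]]
NumericVector cpp_line_extremum(NumericVector img, IntegerVector dim,
                                int axis, int h, bool maximum) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  std::vector<double> line(n);
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < n; ++t) {
        int i = axis == 0 ? t : a;
        int j = axis == 1 ? t : (axis == 0 ? a : b);
        int k = axis == 2 ? t : b;
        line[t] = img[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < n; ++t) {
        int lo = std::max(0, t - h), hi = std::min(n - 1, t + h);
        double e = line[lo];
        for (int p = lo + 1; p <= hi; ++p)
          e = maximum ? std::max(e, line[p]) : std::min(e, line[p]);
        int i = axis == 0 ? t : a;
        int j = axis == 1 ? t : (axis == 0 ? a : b);
        int k = axis == 2 ? t : b;
        out[idx3(i, j, k, nx, ny)] = e;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// raster/FIFO algorithm), 6-connectivity. marker <= mask everywhere.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker,
                                       NumericVector mask,
                                       IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector J = clone(marker);
  R_xlen_t n = J.size();
  for (R_xlen_t t = 0; t < n; ++t)
    if (J[t] > mask[t]) J[t] = mask[t];

  // forward raster: neighbors (-x,-y,-z)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        double m = J[p];
        if (i > 0) m = std::max(m, J[idx3(i - 1, j, k, nx, ny)]);
        if (j > 0) m = std::max(m, J[idx3(i, j - 1, k, nx, ny)]);
        if (k > 0) m = std::max(m, J[idx3(i, j, k - 1, nx, ny)]);
        J[p] = std::min(m, mask[p]);
      }
  // backward raster + queue seeding
  std::queue<int> fifo;
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        int p = idx3(i, j, k, nx, ny);
        double m = J[p];
        if (i < nx - 1) m = std::max(m, J[idx3(i + 1, j, k, nx, ny)]);
        if (j < ny - 1) m = std::max(m, J[idx3(i, j + 1, k, nx, ny)]);
        if (k < nz - 1) m = std::max(m, J[idx3(i, j, k + 1, nx, ny)]);
        J[p] = std::min(m, mask[p]);
        // queue if a backward neighbor could still be raised
        bool push = false;
        if (i < nx - 1) { int q = idx3(i + 1, j, k, nx, ny);
          if (J[q] < J[p] && J[q] < mask[q]) push = true; }
        if (!push && j < ny - 1) { int q = idx3(i, j + 1, k, nx, ny);
          if (J[q] < J[p] && J[q] < mask[q]) push = true; }
        if (!push && k < nz - 1) { int q = idx3(i, j, k + 1, nx, ny);
          if (J[q] < J[p] && J[q] < mask[q]) push = true; }
        if (push) fifo.push(p);
      }
  const int offs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int k = p / (nx * ny), rem = p % (nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int o = 0; o < 6; ++o) {
      int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int q = idx3(ii, jj, kk, nx, ny);
      if (J[q] < J[p] && J[q] < mask[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary volume; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({di, dj, dk});
      }
  int cur = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int k = p / (nx * ny), rem = p % (nx * ny);
      int j = rem / nx, i = rem % nx;
      for (auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int q = idx3(ii, jj, kk, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-based watershed (Meyer flooding, no watershed lines), ascending
// intensity, 6-connectivity. markers: positive integer seeds, 0 elsewhere.
struct WsNode {
  double val; long long ord; int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.val != b.val) return a.val > b.val;   // lower value first
    return a.ord > b.ord;                       // FIFO among ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector img, IntegerVector markers,
                            IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab = clone(markers);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long ord = 0;
  for (R_xlen_t t = 0; t < n; ++t)
    if (lab[t] > 0) pq.push({img[t], ord++, (int)t});
  const int offs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int p = nd.idx;
    int k = p / (nx * ny), rem = p % (nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int o = 0; o < 6; ++o) {
      int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int q = idx3(ii, jj, kk, nx, ny);
      if (lab[q] == 0) {
        lab[q] = lab[p];
        pq.push({std::max(nd.val, img[q]), ord++, q});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Multi-source BFS label propagation restricted to a mask (6-connectivity):
// every mask voxel joins the geodesically nearest seed label.
// [[Rcpp::export]]
IntegerVector cpp_seeded_dilate(IntegerVector seeds, IntegerVector mask,
                                IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::queue<int> fifo;
  for (R_xlen_t t = 0; t < n; ++t)
    if (seeds[t] > 0 && mask[t]) { lab[t] = seeds[t]; fifo.push((int)t); }
  const int offs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int k = p / (nx * ny), rem = p % (nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int o = 0; o < 6; ++o) {
      int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int q = idx3(ii, jj, kk, nx, ny);
      if (mask[q] && lab[q] == 0) { lab[q] = lab[p]; fifo.push(q); }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact minimum distance from points to a triangle soup.
static double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int t = 0; t < 3; ++t) {
    ab[t] = b[t] - a[t]; ac[t] = c[t] - a[t]; ap[t] = p[t] - a[t];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double a00 = ab[0]*ab[0] + ab[1]*ab[1] + ab[2]*ab[2];
  double a01 = ab[0]*ac[0] + ab[1]*ac[1] + ab[2]*ac[2];
  double a11 = ac[0]*ac[0] + ac[1]*ac[1] + ac[2]*ac[2];
  double det = a00 * a11 - a01 * a01;
  double s, t2;
  if (det > 1e-30) {
    s = (a11 * d1 - a01 * d2) / det;
    t2 = (a00 * d2 - a01 * d1) / det;
  } else { s = -1.0; t2 = -1.0; }
  if (s < 0 || t2 < 0 || s + t2 > 1) {
    // clamp to the three edges and take the best
    double best = std::numeric_limits<double>::infinity();
    // edge ab
    double u = a00 > 0 ? clamp01(d1 / a00) : 0.0;
    double dx, dy, dz, dd;
    dx = ap[0] - u*ab[0]; dy = ap[1] - u*ab[1]; dz = ap[2] - u*ab[2];
    dd = dx*dx + dy*dy + dz*dz; if (dd < best) best = dd;
    // edge ac
    u = a11 > 0 ? clamp01(d2 / a11) : 0.0;
    dx = ap[0] - u*ac[0]; dy = ap[1] - u*ac[1]; dz = ap[2] - u*ac[2];
    dd = dx*dx + dy*dy + dz*dz; if (dd < best) best = dd;
    // edge bc
    double bc[3] = {c[0]-b[0], c[1]-b[1], c[2]-b[2]};
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double lbc = bc[0]*bc[0] + bc[1]*bc[1] + bc[2]*bc[2];
    u = lbc > 0 ? clamp01((bc[0]*bp[0]+bc[1]*bp[1]+bc[2]*bp[2]) / lbc) : 0.0;
    dx = bp[0]-u*bc[0]; dy = bp[1]-u*bc[1]; dz = bp[2]-u*bc[2];
    dd = dx*dx + dy*dy + dz*dz; if (dd < best) best = dd;
    return best;
  }
  double q[3];
  for (int t = 0; t < 3; ++t) q[t] = a[t] + s*ab[t] + t2*ac[t];
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// points: n x 3; verts: v x 3; tris: t x 3 (1-based vertex indices)
// [[Rcpp::export]]
NumericVector cpp_mesh_distance(NumericMatrix points, NumericMatrix verts,
                                IntegerMatrix tris) {
  int np = points.nrow(), nt = tris.nrow();
  NumericVector out(np);
  // per-triangle bounding spheres for cheap pruning
  std::vector<double> cx(nt), cy(nt), cz(nt), cr(nt);
  std::vector<double> A(3 * nt), B(3 * nt), C(3 * nt);
  for (int t = 0; t < nt; ++t) {
    int ia = tris(t, 0) - 1, ib = tris(t, 1) - 1, ic = tris(t, 2) - 1;
    for (int u = 0; u < 3; ++u) {
      A[3*t+u] = verts(ia, u); B[3*t+u] = verts(ib, u); C[3*t+u] = verts(ic, u);
    }
    cx[t] = (A[3*t] + B[3*t] + C[3*t]) / 3.0;
    cy[t] = (A[3*t+1] + B[3*t+1] + C[3*t+1]) / 3.0;
    cz[t] = (A[3*t+2] + B[3*t+2] + C[3*t+2]) / 3.0;
    double r2 = 0.0;
    for (const double* V : {&A[3*t], &B[3*t], &C[3*t]}) {
      double dx = V[0]-cx[t], dy = V[1]-cy[t], dz = V[2]-cz[t];
      r2 = std::max(r2, dx*dx + dy*dy + dz*dz);
    }
    cr[t] = std::sqrt(r2);
  }
  for (int p = 0; p < np; ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    double pt[3] = {px, py, pz};
    double best = std::numeric_limits<double>::infinity();
    double bestd = std::sqrt(best);
    for (int t = 0; t < nt; ++t) {
      double dx = px-cx[t], dy = py-cy[t], dz = pz-cz[t];
      double dcen = std::sqrt(dx*dx + dy*dy + dz*dz) - cr[t];
      if (dcen > bestd) continue;
      double d2 = point_tri_dist2(pt, &A[3*t], &B[3*t], &C[3*t]);
      if (d2 < best) { best = d2; bestd = std::sqrt(best); }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a volume at physical points (µm), with the
// center-of-voxel convention: voxel (i,j,k) [0-based] center sits at
// (i + 0.5) * spacing. Clamps to the valid grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector spacing, NumericMatrix points) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double gx = points(p, 0) / spacing[0] - 0.5;
    double gy = points(p, 1) / spacing[1] - 0.5;
    double gz = points(p, 2) / spacing[2] - 0.5;
    gx = std::min(std::max(gx, 0.0), nx - 1.0);
    gy = std::min(std::max(gy, 0.0), ny - 1.0);
    gz = std::min(std::max(gz, 0.0), nz - 1.0);
    int i0 = std::min((int)gx, nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)gy, ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)gz, nz - 2 >= 0 ? nz - 2 : 0);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          int ii = std::min(i0 + di, nx - 1);
          int jj = std::min(j0 + dj, ny - 1);
          int kk = std::min(k0 + dk, nz - 1);
          acc += w * vol[idx3(ii, jj, kk, nx, ny)];
        }
    out[p] = acc;
  }
  return out;
}
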