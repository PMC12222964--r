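// 3D voxel morphology kernels: connected components, hole filling,
// Euclidean distance transform, separable Gaussian smoothing, boundary
// shells, seeded region growing and trilinear resampling after rotation.
// All grids are column-major logical/numeric R arrays with dim = (nx,ny,nz),
// axis order (x, y, z).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// offsets for 6- and 26-connectivity
static void neighbourhood(int conn, std::vector<int>& dx, std::vector<int>& dy,
                          std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (conn == 6) {
    int ox[6] = {1,-1,0,0,0,0}, oy[6] = {0,0,1,-1,0,0}, oz[6] = {0,0,0,0,1,-1};
    for (int t = 0; t < 6; ++t) { dx.push_back(ox[t]); dy.push_back(oy[t]); dz.push_back(oz[t]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbourhood(connectivity, dx, dy, dz);
  int nn = (int)dx.size();
  int cur = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back((int)s);
    lab[s] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
      for (int t = 0; t < nn; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Fill cavities: background voxels (6-connected) not reachable from the
// grid border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1) continue;
        int v = idx3(i, j, k, nx, ny);
        if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
  std::vector<int> dx, dy, dz;
  neighbourhood(6, dx, dy, dz);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int w = idx3(ii, jj, kk, nx, ny);
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = mask[s] || !outside[s];
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on samples at
// positions i*w; f holds squared distances, INF where no source.
// "No source" is encoded as a large finite value so the parabola
// intersections stay finite; callers treat distances above DT_BIG/2 as
// unreachable.
static const double DT_BIG = 1e18;
static void dt1d(std::vector<double>& f, double w, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF; z[1] = INF;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = (f[q] + w2 * q * q - f[v[k]] - w2 * v[k] * v[k]) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0, new parabola dominates everywhere
      v[0] = q;
      z[0] = -INF; z[1] = INF;
      k = 0;
      continue;
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = std::min(d[q], DT_BIG);
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest source voxel centre. Anisotropic pitch supported.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector source, IntegerVector dims, NumericVector pitch) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t s = 0; s < n; ++s) g[s] = source[s] ? 0.0 : DT_BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      f.resize(nx);
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, pitch[0], d, v, z);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = f[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      f.resize(ny);
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, pitch[1], d, v, z);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = f[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      f.resize(nz);
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, pitch[2], d, v, z);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = f[k];
    }
  return g;
}

// Separable Gaussian smoothing, sigma in voxels per axis, reflecting edges.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector field, IntegerVector dims, NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector a = clone(field);
  NumericVector b(n);
  int nn[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + r]; }
    for (double& kv : ker) kv /= sum;
    int len = nn[ax];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          int pos[3] = {i, j, k};
          for (int t = -r; t <= r; ++t) {
            int q = pos[ax] + t;
            if (q < 0) q = -q - 1;
            if (q >= len) q = 2 * len - q - 1;
            int p2[3] = {i, j, k};
            p2[ax] = q;
            acc += ker[t + r] * a[idx3(p2[0], p2[1], p2[2], nx, ny)];
          }
          b[idx3(i, j, k, nx, ny)] = acc;
        }
    std::swap(a, b);
  }
  return a;
}

// 6-connectivity boundary shell: mask voxels with a face neighbour outside
// the mask (or on the grid border).
// [[Rcpp::export]]
LogicalVector cpp_shell6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<int> dx, dy, dz;
  neighbourhood(6, dx, dy, dz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (!mask[v]) continue;
        bool edge = false;
        for (int t = 0; t < 6 && !edge; ++t) {
          int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) edge = true;
          else if (!mask[idx3(ii, jj, kk, nx, ny)]) edge = true;
        }
        out[v] = edge;
      }
  return out;
}

// Seeded region growing: FIFO breadth-first flood (26-connected) restricted
// to `allowed`; a voxel joins when |value - running mean| <= tol.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector ri, IntegerVector dims, LogicalVector allowed,
                              int seed0, double tol) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<char> seen(n, 0);
  std::vector<int> dx, dy, dz;
  neighbourhood(26, dx, dy, dz);
  std::queue<int> q;
  double sum = ri[seed0];
  long cnt = 1;
  out[seed0] = true; seen[seed0] = 1;
  q.push(seed0);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
    double mean = sum / cnt;
    for (int t = 0; t < 26; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int w = idx3(ii, jj, kk, nx, ny);
      if (seen[w] || !allowed[w]) continue;
      seen[w] = 1;
      // 1e-9 guard absorbs running-mean float drift so tol = 0 means
      // "equal values", not "bit-identical partial sums"
      if (std::fabs(ri[w] - mean) <= tol + 1e-9) {
        out[w] = true;
        sum += ri[w]; ++cnt;
        q.push(w);
      }
    }
  }
  return out;
}

// Trilinear resampling of `field` after rigid rotation about the volume
// centre. R9 is the row-major 3x3 rotation matrix mapping input coords to
// output coords; we evaluate input at R^T (x - c) + c. Physical pitch aware.
// [[Rcpp::export]]
NumericVector cpp_rotate_trilinear(NumericVector field, IntegerVector dims,
                                   NumericVector pitch, NumericVector R9) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);
  double cx = 0.5 * nx * pitch[0], cy = 0.5 * ny * pitch[1], cz = 0.5 * nz * pitch[2];
  // inverse rotation = transpose
  double r[9];
  r[0] = R9[0]; r[1] = R9[3]; r[2] = R9[6];
  r[3] = R9[1]; r[4] = R9[4]; r[5] = R9[7];
  r[6] = R9[2]; r[7] = R9[5]; r[8] = R9[8];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * pitch[0] - cx;
        double y = (j + 0.5) * pitch[1] - cy;
        double z = (k + 0.5) * pitch[2] - cz;
        double sx = r[0] * x + r[1] * y + r[2] * z + cx;
        double sy = r[3] * x + r[4] * y + r[5] * z + cy;
        double sz = r[6] * x + r[7] * y + r[8] * z + cz;
        double fi = sx / pitch[0] - 0.5, fj = sy / pitch[1] - 0.5, fk = sz / pitch[2] - 0.5;
        int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
        double ti = fi - i0, tj = fj - j0, tk = fk - k0;
        double acc = 0;
        for (int a = 0; a <= 1; ++a)
          for (int b = 0; b <= 1; ++b)
            for (int c = 0; c <= 1; ++c) {
              int ii = i0 + a, jj = j0 + b, kk = k0 + c;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              double wgt = (a ? ti : 1 - ti) * (b ? tj : 1 - tj) * (c ? tk : 1 - tk);
              acc += wgt * field[idx3(ii, jj, kk, nx, ny)];
            }
        out[idx3(i, j, k, nx, ny)] = acc;
      }
  return out;
}
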