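// Incremental 3D convex hull (double precision, deterministic insertion
// order) plus half-space voxelization. Hulls are computed in voxel-index
// space: convexity is invariant under the anisotropic index->physical
// scaling, so voxel membership is unaffected.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <array>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;      // unit outward normal
  double off;  // n . vertex
  bool alive;
};

struct Hull {
  std::vector<Vec3> pts;
  std::vector<Face> faces;
  Vec3 interior;
  bool ok;
};

static bool makeFace(Hull& h, int a, int b, int c, Face& f) {
  Vec3 nr = cross(sub(h.pts[b], h.pts[a]), sub(h.pts[c], h.pts[a]));
  double ln = norm(nr);
  if (ln < 1e-12) return false;
  nr.x /= ln; nr.y /= ln; nr.z /= ln;
  double off = dot(nr, h.pts[a]);
  if (dot(nr, h.interior) > off) { // flip to outward
    std::swap(b, c);
    nr.x = -nr.x; nr.y = -nr.y; nr.z = -nr.z;
    off = -off;
  }
  f.a = a; f.b = b; f.c = c; f.n = nr; f.off = off; f.alive = true;
  return true;
}

static Hull buildHull(const NumericMatrix& P) {
  Hull h;
  h.ok = false;
  int n = P.nrow();
  h.pts.resize(n);
  double scale = 1.0;
  for (int i = 0; i < n; ++i) {
    h.pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
    scale = std::max(scale, std::fabs(P(i, 0)));
    scale = std::max(scale, std::fabs(P(i, 1)));
    scale = std::max(scale, std::fabs(P(i, 2)));
  }
  if (n < 4) return h;
  const double eps = 1e-9 * scale;
  // initial extremes
  int p0 = 0;
  for (int i = 1; i < n; ++i) {
    const Vec3 &a = h.pts[i], &b = h.pts[p0];
    if (a.x < b.x || (a.x == b.x && (a.y < b.y || (a.y == b.y && a.z < b.z)))) p0 = i;
  }
  int p1 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d = norm(sub(h.pts[i], h.pts[p0]));
    if (d > best) { best = d; p1 = i; }
  }
  if (p1 < 0) return h;
  int p2 = -1; best = eps;
  Vec3 d01 = sub(h.pts[p1], h.pts[p0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(d01, sub(h.pts[i], h.pts[p0]))) / norm(d01);
    if (d > best) { best = d; p2 = i; }
  }
  if (p2 < 0) return h;
  Vec3 nrm = cross(d01, sub(h.pts[p2], h.pts[p0]));
  double ln = norm(nrm);
  nrm.x /= ln; nrm.y /= ln; nrm.z /= ln;
  int p3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(h.pts[i], h.pts[p0])));
    if (d > best) { best = d; p3 = i; }
  }
  if (p3 < 0) return h; // coplanar input
  h.interior = {(h.pts[p0].x + h.pts[p1].x + h.pts[p2].x + h.pts[p3].x) / 4.0,
                (h.pts[p0].y + h.pts[p1].y + h.pts[p2].y + h.pts[p3].y) / 4.0,
                (h.pts[p0].z + h.pts[p1].z + h.pts[p2].z + h.pts[p3].z) / 4.0};
  Face f;
  int tet[4][3] = {{p0, p1, p2}, {p0, p1, p3}, {p0, p2, p3}, {p1, p2, p3}};
  for (int t = 0; t < 4; ++t) {
    if (!makeFace(h, tet[t][0], tet[t][1], tet[t][2], f)) return h;
    h.faces.push_back(f);
  }
  const double veps = 1e-7 * scale;
  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    visible.clear();
    for (size_t fi = 0; fi < h.faces.size(); ++fi) {
      if (!h.faces[fi].alive) continue;
      if (dot(h.faces[fi].n, h.pts[i]) > h.faces[fi].off + veps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue;
    // horizon: undirected edges used exactly once among visible faces
    std::map<std::pair<int, int>, std::pair<int, int>> edges; // undirected -> (count, directed u)
    for (int fi : visible) {
      const Face& fc = h.faces[fi];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int t = 0; t < 3; ++t) {
        int u = e[t][0], v = e[t][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v) : std::make_pair(v, u);
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = {1, u};
        else it->second.first += 1;
      }
    }
    for (int fi : visible) h.faces[fi].alive = false;
    for (auto& kv : edges) {
      if (kv.second.first != 1) continue;
      int u = kv.second.second;
      int v = (u == kv.first.first) ? kv.first.second : kv.first.first;
      if (makeFace(h, u, v, i, f)) h.faces.push_back(f);
    }
  }
  // compact
  std::vector<Face> keep;
  for (const Face& fc : h.faces) if (fc.alive) keep.push_back(fc);
  h.faces.swap(keep);
  h.ok = !h.faces.empty();
  return h;
}

static double hullVolume(const Hull& h) {
  double vol = 0;
  for (const Face& fc : h.faces) {
    Vec3 a = sub(h.pts[fc.a], h.interior);
    Vec3 b = sub(h.pts[fc.b], h.interior);
    Vec3 c = sub(h.pts[fc.c], h.interior);
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return std::fabs(vol);
}

// mark voxels (index-space integer centres) inside the hull, within bbox,
// into `out` (length prod(dims), 0-based linear index layout)
static void rasterHull(const Hull& h, const int lo[3], const int hi[3],
                       const IntegerVector& dims, std::vector<char>& out) {
  int nx = dims[0], ny = dims[1];
  const double beps = 1e-6;
  for (int j = lo[1]; j <= hi[1]; ++j)
    for (int i = lo[0]; i <= hi[0]; ++i) {
      double zlo = lo[2], zhi = hi[2];
      bool empty = false;
      for (const Face& fc : h.faces) {
        double c = fc.n.z;
        double num = fc.off - fc.n.x * i - fc.n.y * j;
        if (c > 1e-12) zhi = std::min(zhi, (num + beps) / c);
        else if (c < -1e-12) zlo = std::max(zlo, (num + beps) / c);
        else if (num < -beps) { empty = true; break; }
      }
      if (empty) continue;
      int k0 = (int)std::ceil(zlo - 1e-9), k1 = (int)std::floor(zhi + 1e-9);
      for (int k = std::max(k0, lo[2]); k <= std::min(k1, hi[2]); ++k)
        out[i + nx * (j + (R_xlen_t)ny * k)] = 1;
    }
}

} // namespace

// [[Rcpp::export]]
List cpp_hull_points(NumericMatrix pts) {
  Hull h = buildHull(pts);
  if (!h.ok) return List::create(_["ok"] = false, _["volume"] = 0.0);
  return List::create(_["ok"] = true, _["volume"] = hullVolume(h),
                      _["nfaces"] = (int)h.faces.size());
}

// Voxelized convex hull of integer points `pts` on a grid of size `dims`
// (0-based indices). Returns a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_voxel_hull(NumericMatrix pts, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> out(n, 0);
  Hull h = buildHull(pts);
  LogicalVector res(n, false);
  if (!h.ok) { // degenerate: just mark the input points
    for (int i = 0; i < pts.nrow(); ++i) {
      int a = (int)pts(i, 0), b = (int)pts(i, 1), c = (int)pts(i, 2);
      if (a >= 0 && b >= 0 && c >= 0 && a < nx && b < ny && c < nz)
        res[a + nx * (b + (R_xlen_t)ny * c)] = true;
    }
    return res;
  }
  int lo[3] = {nx - 1, ny - 1, nz - 1}, hi[3] = {0, 0, 0};
  for (int i = 0; i < pts.nrow(); ++i) {
    int q[3] = {(int)pts(i, 0), (int)pts(i, 1), (int)pts(i, 2)};
    for (int t = 0; t < 3; ++t) {
      lo[t] = std::min(lo[t], q[t]);
      hi[t] = std::max(hi[t], q[t]);
    }
  }
  for (int t = 0; t < 3; ++t) { lo[t] = std::max(lo[t], 0); }
  hi[0] = std::min(hi[0], nx - 1); hi[1] = std::min(hi[1], ny - 1); hi[2] = std::min(hi[2], nz - 1);
  rasterHull(h, lo, hi, dims, out);
  for (R_xlen_t s = 0; s < n; ++s) res[s] = out[s] != 0;
  return res;
}

// Exact hull volume of a point cloud (used for the convexity index).
// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  Hull h = buildHull(pts);
  if (!h.ok) return 0.0;
  return hullVolume(h);
}

// Local pairwise linking: for every pair of sub-cubes whose physical centres
// are within `radius`, rasterize the convex hull of the union of their voxel
// sets; the result is OR-ed with all cube voxels. cubeVoxels holds 1-based
// linear indices per cube.
// [[Rcpp::export]]
List cpp_link_pairs(List cubeVoxels, NumericMatrix centers, IntegerVector dims,
                    NumericVector pitch, double radius) {
  int nc = cubeVoxels.size();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> out(n, 0);
  // decode voxel coordinates once
  std::vector<std::vector<std::array<int, 3>>> coords(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector vi = cubeVoxels[c];
    coords[c].resize(vi.size());
    for (int t = 0; t < vi.size(); ++t) {
      int v = vi[t] - 1;
      int k = v / (nx * ny), r = v % (nx * ny);
      coords[c][t] = {r % nx, r / nx, k};
      out[v] = 1;
    }
  }
  double r2 = radius * radius;
  int npairs = 0;
  for (int a = 0; a < nc; ++a)
    for (int b = a + 1; b < nc; ++b) {
      double dx = (centers(a, 0) - centers(b, 0)) * pitch[0];
      double dy = (centers(a, 1) - centers(b, 1)) * pitch[1];
      double dz = (centers(a, 2) - centers(b, 2)) * pitch[2];
      if (dx * dx + dy * dy + dz * dz > r2) continue;
      ++npairs;
      int np = (int)(coords[a].size() + coords[b].size());
      NumericMatrix P(np, 3);
      int lo[3] = {nx - 1, ny - 1, nz - 1}, hi[3] = {0, 0, 0};
      int row = 0;
      for (int src = 0; src < 2; ++src) {
        const auto& cs = coords[src == 0 ? a : b];
        for (const auto& q : cs) {
          P(row, 0) = q[0]; P(row, 1) = q[1]; P(row, 2) = q[2];
          for (int t = 0; t < 3; ++t) {
            lo[t] = std::min(lo[t], q[t]);
            hi[t] = std::max(hi[t], q[t]);
          }
          ++row;
        }
      }
      Hull h = buildHull(P);
      if (h.ok) rasterHull(h, lo, hi, dims, out);
    }
  LogicalVector res(n, false);
  for (R_xlen_t s = 0; s < n; ++s) res[s] = out[s] != 0;
  return List::create(_["mask"] = res, _["npairs"] = npairs);
}
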