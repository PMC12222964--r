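// Fourier-support (OTF) occupancy builders. A voxel is occupied when its
// centre lies inside the solid swept by the Ewald caps of the acquisition
// geometry; evaluating the continuous sweep per voxel keeps the voxelized
// volume free of the half-voxel surface bias a cap-by-cap rasterization
// would add.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample rotation about kx: the upper Ewald cap
//   kz = k0 - sqrt(k0^2 - kx^2 - ky^2), kx^2 + ky^2 <= a^2
// swept through 360 degrees fills, at each kx, the annulus between
//   rho_min = k0 - sqrt(k0^2 - kx^2)  (cap apex) and
//   rho_max = sqrt((a^2 - kx^2) + (k0 - c)^2) (cap rim), c = sqrt(k0^2 - a^2).
// [[Rcpp::export]]
LogicalVector cpp_otf_rotation(IntegerVector dims, NumericVector step3,
                               double k0, double a) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = step3[0], hy = step3[1], hz = step3[2];
  double c = std::sqrt(k0 * k0 - a * a);
  double rimz = k0 - c;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  int cx = nx / 2, cy = ny / 2, cz = nz / 2;
  const double eps = 1e-9;
  for (int k = 0; k < nz; ++k) {
    double kz = (k - cz) * hz;
    for (int j = 0; j < ny; ++j) {
      double ky = (j - cy) * hy;
      double rho2 = ky * ky + kz * kz;
      for (int i = 0; i < nx; ++i) {
        double kx = (i - cx) * hx;
        if (std::fabs(kx) > a + eps) continue;
        double kx2 = kx * kx;
        double rmin = k0 - std::sqrt(std::max(k0 * k0 - kx2, 0.0));
        double rmax2 = std::max(a * a - kx2, 0.0) + rimz * rimz;
        if (rho2 <= rmax2 + eps && rho2 >= rmin * rmin - eps)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// Illumination scanning in the y-z plane: incident wavevectors
// k0 (0, sin t, cos t) with |sin t| <= a / k0, detection limited to scattered
// lateral frequency <= a. At a lateral position (kx, ky) the union of the
// shifted caps covers kz in [gmin, gmax] where
//   g(t) = sqrt(k0^2 - kx^2 - (ky + t)^2) - sqrt(k0^2 - t^2)
// over the feasible illumination range; the support is then symmetrized
// under k -> -k.
// [[Rcpp::export]]
LogicalVector cpp_otf_scan(IntegerVector dims, NumericVector step3,
                           double k0, double a, int ntheta) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = step3[0], hy = step3[1], hz = step3[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  int cx = nx / 2, cy = ny / 2, cz = nz / 2;
  double thetaMax = std::asin(a / k0);
  const double eps = 1e-9;
  for (int j = 0; j < ny; ++j) {
    double ky = (j - cy) * hy;
    for (int i = 0; i < nx; ++i) {
      double kx = (i - cx) * hx;
      double kx2 = kx * kx;
      if (kx2 > a * a + eps) continue;
      // feasible incident lateral frequencies: |t| <= b and |ky + t| <= s
      double b = k0 * std::sin(thetaMax);
      double s = std::sqrt(std::max(a * a - kx2, 0.0));
      double t0 = std::max(-b, -ky - s), t1 = std::min(b, -ky + s);
      if (t1 < t0) continue;
      double gmin = R_PosInf, gmax = R_NegInf;
      for (int t = 0; t < ntheta; ++t) {
        double ti = t0 + (t1 - t0) * t / (ntheta - 1.0);
        double sy = ky + ti;
        double lat2 = kx2 + sy * sy;
        if (lat2 > a * a) lat2 = a * a;
        double g = std::sqrt(std::max(k0 * k0 - lat2, 0.0)) -
                   std::sqrt(std::max(k0 * k0 - ti * ti, 0.0));
        if (g < gmin) gmin = g;
        if (g > gmax) gmax = g;
      }
      if (gmin > gmax) continue;
      for (int k = 0; k < nz; ++k) {
        double kz = (k - cz) * hz;
        bool inside = (kz >= gmin - eps && kz <= gmax + eps) ||
                      (-kz >= gmin - eps && -kz <= gmax + eps);
        if (inside) out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}
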