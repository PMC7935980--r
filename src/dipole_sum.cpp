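#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of point-dipole flux densities at evaluation points.
// All dipole moments point along +x with per-dipole magnitude mom (A m^2);
// this is the raster representation of x-magnetized micromagnets.
// pts: n x 3 (m), dip: m x 3 (m). Returns n x 3 flux density in tesla.
// [[Rcpp::export]]
NumericMatrix dipole_sum_x(NumericMatrix pts, NumericMatrix dip, NumericVector mom) {
  const double k = 1e-7; // mu0 / (4 pi)
  const int n = pts.nrow(), m = dip.nrow();
  if (dip.nrow() != mom.size())
    stop("moment vector length must match dipole count");
  std::vector<double> dx(m), dy(m), dz(m), mm(m);
  for (int j = 0; j < m; ++j) {
    dx[j] = dip(j, 0); dy[j] = dip(j, 1); dz[j] = dip(j, 2);
    mm[j] = k * mom[j];
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double bx = 0.0, by = 0.0, bz = 0.0;
    for (int j = 0; j < m; ++j) {
      const double rx = px - dx[j], ry = py - dy[j], rz = pz - dz[j];
      const double r2 = rx * rx + ry * ry + rz * rz;
      const double r = std::sqrt(r2);
      const double inv_r3 = 1.0 / (r2 * r);
      const double inv_r5 = inv_r3 / r2;
      const double c = mm[j];
      bx += c * (3.0 * rx * rx * inv_r5 - inv_r3);
      by += c * 3.0 * rx * ry * inv_r5;
      bz += c * 3.0 * rx * rz * inv_r5;
    }
    out(i, 0) = bx; out(i, 1) = by; out(i, 2) = bz;
  }
  return out;
}
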