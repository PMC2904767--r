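#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Golden-spiral quadrature on the unit sphere: deterministic, near-uniform.
static std::vector<double> sphere_points(const int n) {
  std::vector<double> pts(3 * n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    pts[3 * k] = r * std::cos(phi);
    pts[3 * k + 1] = r * std::sin(phi);
    pts[3 * k + 2] = z;
  }
  return pts;
}

// Shrake-Rupley accessible surface area, one value per atom (A^2).
// coords: n x 3 (Angstrom); radii: van der Waals radii per atom.
// [[Rcpp::export]]
NumericVector sasa_atoms_cpp(const NumericMatrix& coords,
                             const NumericVector& radii,
                             const double probe,
                             const int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  std::vector<double> pts = sphere_points(n_points);
  std::vector<int> nb;
  nb.reserve(64);

  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double lim = ri + radii[j] + probe;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int n_acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = xi + ri * pts[3 * k];
      const double py = yi + ri * pts[3 * k + 1];
      const double pz = zi + ri * pts[3 * k + 2];
      bool acc = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { acc = false; break; }
      }
      if (acc) ++n_acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * static_cast<double>(n_acc) / n_points;
  }
  return area;
}

// Minimum interatomic distance; brute-force pair scan used by the
// synthetic generator's clash guard and its tests.
// [[Rcpp::export]]
double min_pair_distance_cpp(const NumericMatrix& coords) {
  const int n = coords.nrow();
  if (n < 2) return R_PosInf;
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
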