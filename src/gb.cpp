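#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise-descreening integrals of the Hawkins-Cramer-Truhlar scheme.
// rho_red: reduced intrinsic radii (rho_i - offset); sdesc: S_j * rho_red_j,
// the scaled descreening radii. Returns I_i with units 1/Angstrom.
// [[Rcpp::export]]
NumericVector hct_integrals_cpp(const NumericMatrix& coords,
                                const NumericVector& rho_red,
                                const NumericVector& sdesc) {
  const int n = coords.nrow();
  NumericVector I(n);
  for (int i = 0; i < n; ++i) {
    const double ri = rho_red[i];
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double sj = sdesc[j];
      if (ri >= r + sj) continue;   // neighbour fully inside atom i
      const double U = r + sj;
      double L = std::fabs(r - sj);
      if (L < ri) L = ri;
      double term = 1.0 / L - 1.0 / U
        + 0.25 * (1.0 / (U * U) - 1.0 / (L * L)) * (r - sj * sj / r)
        + 0.5 * std::log(L / U) / r;
      if (sj > r + ri) term += 2.0 * (1.0 / ri - 1.0 / L);  // engulfed case
      acc += 0.5 * term;
    }
    I[i] = acc;
  }
  return I;
}

// Generalized Born double sum: S = sum_i q_i^2/(2 R_i)
//   + sum_{i<j} q_i q_j / f_GB(r_ij, R_i, R_j),
// f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj))).
// The polar solvation energy is -tau * k_C * S (applied by the caller).
// cutoff <= 0 means no cutoff (exact double sum, the reference path).
// [[Rcpp::export]]
double gb_pair_sum_cpp(const NumericMatrix& coords,
                       const NumericVector& q,
                       const NumericVector& reff,
                       const double cutoff) {
  const int n = coords.nrow();
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += 0.5 * q[i] * q[i] / reff[i];
  const bool use_cut = cutoff > 0.0;
  const double cut2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    if (q[i] == 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (q[j] == 0.0) continue;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cut && r2 > cut2) continue;
      const double rr = reff[i] * reff[j];
      const double f = std::sqrt(r2 + rr * std::exp(-r2 / (4.0 * rr)));
      S += q[i] * q[j] / f;
    }
  }
  return S;
}
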