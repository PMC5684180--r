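// Asynchronous multi-state Hopfield recall dynamics.
//
// The only hot loop in the package: one call runs a full trajectory of
// random-permutation sweeps with optional Gaussian field noise and
// per-neuron FAS injury regimes.  Uses R's RNG (norm_rand / unif_rand) so
// set.seed() on the R side makes trajectories bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// Effective transmitted output (bipolar scale) of a neuron at bipolar value
// v under injury regime `regime`.  The transfer function acts on the
// magnitude of the transmitted signal and preserves its sign, so the
// severity ordering is transmission > filtering > reflection > blockage.
// Regimes: 0 uninjured, 1 transmission, 2 filtering (piecewise-linear soft
// cap of strong signals), 3 reflection (signal halving), 4 blockage (no
// signal passes: contributes nothing to downstream fields).
static inline double out_value(double v, int regime, double theta_f, double kappa) {
  switch (regime) {
  case 0:
  case 1:
    return v;
  case 2: {
    double m = std::fabs(v);
    double mt = (m <= theta_f) ? m : theta_f + kappa * (m - theta_f);
    return (v >= 0.0) ? mt : -mt;
  }
  case 3:
    return 0.5 * v;
  case 4:
    return 0.0;
  default:
    stop("unknown injury regime");
  }
  return 0.0; // unreachable
}

// [[Rcpp::export]]
List cpp_run_dynamics(const NumericMatrix& W, const IntegerVector& levels0,
                      const NumericVector& level_values,
                      const NumericVector& center, double noise_sigma,
                      const IntegerVector& regime, double theta_f, double kappa,
                      int max_sweeps, bool single_sweep) {
  const int n = W.nrow();
  const int q = level_values.size();
  if (W.ncol() != n || levels0.size() != n || regime.size() != n ||
      center.size() != n)
    stop("dimension mismatch between weights, state and injury assignment");
  if (max_sweeps < 1) stop("max_sweeps must be >= 1");

  std::vector<int> lev(levels0.begin(), levels0.end());
  // Blocked neurons are silenced: their effective firing rate (= state) is
  // zero, so they sit at the lowest activity level, frozen, and transmit
  // nothing for the whole trajectory.
  for (int j = 0; j < n; ++j)
    if (regime[j] == 4) lev[j] = 0;
  // transmitted signal = activity measured from the reference activity
  std::vector<double> vout(n);
  for (int j = 0; j < n; ++j)
    vout[j] = out_value(level_values[lev[j]] - center[j], regime[j], theta_f, kappa);

  const double* w = REAL(W);
  std::vector<int> perm(n);
  const int quiet_needed = (noise_sigma > 0.0) ? 2 : 1;
  int quiet = 0, sweeps = 0;
  bool converged = false;

  for (int s = 0; s < max_sweeps; ++s) {
    // Fisher-Yates permutation from R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int changes = 0;
    for (int t = 0; t < n; ++t) {
      const int i = perm[t];
      if (regime[i] == 4) continue; // blocked neurons are frozen
      const double* col = w + (size_t)i * n; // column i == row i (symmetric W)
      double h = center[i];
      for (int j = 0; j < n; ++j) h += col[j] * vout[j];
      double u = h;
      if (noise_sigma > 0.0) u += noise_sigma * norm_rand();
      if (u < -1.0) u = -1.0; else if (u > 1.0) u = 1.0;
      // nearest level, exact ties toward the lower level index
      double x = (u + 1.0) * (q - 1) / 2.0;
      int k = (int)std::ceil(x - 0.5);
      if (k < 0) k = 0; else if (k > q - 1) k = q - 1;
      if (k != lev[i]) {
        lev[i] = k;
        vout[i] = out_value(level_values[k] - center[i], regime[i], theta_f, kappa);
        ++changes;
      }
    }
    ++sweeps;
    if (changes == 0) {
      if (++quiet >= quiet_needed) { converged = true; break; }
    } else {
      quiet = 0;
    }
    if (single_sweep) break;
  }

  return List::create(_["levels"] = IntegerVector(lev.begin(), lev.end()),
                      _["converged"] = converged,
                      _["sweeps"] = sweeps);
}
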