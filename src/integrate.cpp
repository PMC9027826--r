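#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of the seven-population rate model
//   tau_j dr_j/dt = -r_j + S_j(sum_i W[i][j] r_i + bg_j + drive at DCN)
// `drive` is sampled on the step grid (length n_steps + 1); RK4 mid-step
// values use linear interpolation between grid nodes. Integration aborts
// with an error naming the step if the state goes non-finite.

static inline double sigmoid(double x, double M, double b, double th) {
  return M / (1.0 + std::exp(-b * (x - th)));
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cctc_integrate_cpp(NumericVector r0, NumericMatrix W,
                                 NumericVector tau, NumericVector max_rate,
                                 NumericVector slope, NumericVector threshold,
                                 NumericVector background, NumericVector drive,
                                 double dt, int dcn_index, int method) {
  const int np = r0.size();
  const int n_steps = drive.size() - 1;
  NumericMatrix out(n_steps + 1, np);
  std::vector<double> r(np), k1(np), k2(np), k3(np), k4(np), tmp(np);

  for (int j = 0; j < np; ++j) { r[j] = r0[j]; out(0, j) = r0[j]; }

  auto deriv = [&](const std::vector<double> &state, double drv,
                   std::vector<double> &d) {
    for (int j = 0; j < np; ++j) {
      double x = background[j];
      for (int i = 0; i < np; ++i) x += W(i, j) * state[i];
      if (j == dcn_index) x += drv;
      d[j] = (-state[j] + sigmoid(x, max_rate[j], slope[j], threshold[j])) / tau[j];
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    const double d0 = drive[s], d1 = drive[s + 1], dm = 0.5 * (d0 + d1);
    if (method == 1) {                      // explicit Euler
      deriv(r, d0, k1);
      for (int j = 0; j < np; ++j) r[j] += dt * k1[j];
    } else {                                // RK4
      deriv(r, d0, k1);
      for (int j = 0; j < np; ++j) tmp[j] = r[j] + 0.5 * dt * k1[j];
      deriv(tmp, dm, k2);
      for (int j = 0; j < np; ++j) tmp[j] = r[j] + 0.5 * dt * k2[j];
      deriv(tmp, dm, k3);
      for (int j = 0; j < np; ++j) tmp[j] = r[j] + dt * k3[j];
      deriv(tmp, d1, k4);
      for (int j = 0; j < np; ++j)
        r[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    for (int j = 0; j < np; ++j) {
      if (!std::isfinite(r[j]))
        stop("integration failure: non-finite state at step %d (t = %g s); "
             "reduce dt", s + 1, (s + 1) * dt);
      out(s + 1, j) = r[j];
    }
  }
  return out;
}
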