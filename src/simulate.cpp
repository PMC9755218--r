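#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Term-encoded function evaluation.  A term matrix has one row per term:
// [coef, e_1..e_M, trig, trigvar, tmod] where trig is 0/1/2 for
// none/sin/cos of variable `trigvar` (1-based) and tmod multiplies the
// term by cos(omega * t).
static inline double eval_terms(const NumericMatrix &T, const double *x,
                                int M, double coswt) {
  double out = 0.0;
  const int K = T.nrow();
  for (int k = 0; k < K; ++k) {
    double v = T(k, 0);
    for (int j = 0; j < M; ++j) {
      int e = (int)T(k, 1 + j);
      for (int p = 0; p < e; ++p) v *= x[j];
    }
    const int trig = (int)T(k, M + 1);
    if (trig == 1)
      v *= std::sin(x[(int)T(k, M + 2) - 1]);
    else if (trig == 2)
      v *= std::cos(x[(int)T(k, M + 2) - 1]);
    if ((int)T(k, M + 3) == 1) v *= coswt;
    out += v;
  }
  return out;
}

// Euler-Maruyama integration (Ito convention: coefficients evaluated at
// the left endpoint).  One standard-normal draw per component per step,
// component index fastest, taken from R's RNG so that set.seed() governs
// reproducibility.  Optionally applies a Gaussian-weighted control force
// c_l = -Theta_l(x) w exp(-(x_l - mu_l)^2 / zeta_l) whose applied values
// are recorded alongside the trajectory.
// [[Rcpp::export]]
List em_simulate_cpp(List drift_terms, List diff_terms, NumericVector x0,
                     double dt, int n_steps, double t0, double omega,
                     bool has_control, List ctrl_terms, NumericVector mu,
                     NumericVector zeta) {
  const int M = x0.size();
  NumericMatrix X(n_steps + 1, M);
  NumericMatrix C(has_control ? n_steps : 0, has_control ? M : 0);
  std::vector<double> x(M), xn(M);
  for (int j = 0; j < M; ++j) { x[j] = x0[j]; X(0, j) = x0[j]; }

  std::vector<NumericMatrix> g(M), h(M), c(M);
  for (int j = 0; j < M; ++j) {
    g[j] = as<NumericMatrix>(drift_terms[j]);
    h[j] = as<NumericMatrix>(diff_terms[j]);
    if (has_control) c[j] = as<NumericMatrix>(ctrl_terms[j]);
  }

  for (int i = 0; i < n_steps; ++i) {
    const double t = t0 + i * dt;
    const double coswt = std::cos(omega * t);
    for (int j = 0; j < M; ++j) {
      double drift = eval_terms(g[j], x.data(), M, coswt);
      double D2 = eval_terms(h[j], x.data(), M, coswt);
      if (!(D2 >= 0.0))
        stop("diffusion coefficient negative at step %d (component %d)",
             i + 1, j + 1);
      double ctrl = 0.0;
      if (has_control) {
        double dxm = x[j] - mu[j];
        ctrl = -eval_terms(c[j], x.data(), M, coswt) *
               std::exp(-(dxm * dxm) / zeta[j]);
        C(i, j) = ctrl;
      }
      xn[j] = x[j] + (drift + ctrl) * dt +
              std::sqrt(2.0 * D2 * dt) * norm_rand();
      if (!std::isfinite(xn[j]))
        stop("trajectory blow-up at step %d (last valid index %d)", i + 1, i);
    }
    for (int j = 0; j < M; ++j) { x[j] = xn[j]; X(i + 1, j) = x[j]; }
  }
  return List::create(_["X"] = X, _["control"] = C);
}
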