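#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the prevalence ODE along the age characteristic,
// expressed in the fitted quantities (all-cause hazard m and MRR R):
//   dp/da = (1-p) * ( i - p * m * (R-1) / (1 + p*(R-1)) )
static inline double prev_rhs(double p, double i, double m, double R) {
  return (1.0 - p) * (i - p * m * (R - 1.0) / (1.0 + p * (R - 1.0)));
}

// Classical fixed-step RK4 on a uniform age grid with step h.
// i_n, m_n, R_n: incidence, hazard, MRR at the n grid nodes;
// i_m, m_m, R_m: the same at the n-1 midpoints.  Boundary p(0) = 0.
// [[Rcpp::export(name = ".rk4_prevalence")]]
NumericVector rk4_prevalence(double h, NumericVector i_n, NumericVector i_m,
                             NumericVector m_n, NumericVector m_m,
                             NumericVector R_n, NumericVector R_m) {
  const int n = i_n.size();
  NumericVector p(n);
  double pk = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double k1 = prev_rhs(pk,                i_n[k],     m_n[k],     R_n[k]);
    double k2 = prev_rhs(pk + 0.5 * h * k1, i_m[k],     m_m[k],     R_m[k]);
    double k3 = prev_rhs(pk + 0.5 * h * k2, i_m[k],     m_m[k],     R_m[k]);
    double k4 = prev_rhs(pk + h * k3,       i_n[k + 1], m_n[k + 1], R_n[k + 1]);
    pk += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!std::isfinite(pk) || pk < 0.0 || pk >= 1.0)
      stop("prevalence left [0,1) at grid index %d (p = %g)", k + 1, pk);
    p[k + 1] = pk;
  }
  return p;
}
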