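#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum a Legendre series per evaluation point, with a geometric tail summed
// in closed form through the generating function
//   sum_n t^n P_n(u) = 1 / sqrt(1 - 2 t u + t^2).
//
// coef: (nterms x npairs) radial coefficients c_n, one column per unique
//       radial pair; A, t: per-pair geometric tail fit c_n ~ A t^n beyond
//       the last computed term; pair: 0-based column index per evaluation
//       point; u: cos(angle) per evaluation point.
// [[Rcpp::export(name = ".legendre_series_sum")]]
NumericVector legendre_series_sum(NumericMatrix coef, NumericVector A,
                                  NumericVector t, IntegerVector pair,
                                  NumericVector u) {
  const int E = u.size();
  const int N = coef.nrow();
  NumericVector out(E);
  for (int e = 0; e < E; ++e) {
    const int p = pair[e];
    const double ue = u[e];
    const double tp = t[p];
    const double Ap = A[p];
    double pm1 = 1.0;      // P_0
    double pn = ue;        // P_1
    double S = coef(0, p);
    double T = 1.0;
    double tpow = tp;
    if (N > 1) {
      S += coef(1, p) * pn;
      T += tpow * pn;
    }
    for (int n = 2; n < N; ++n) {
      const double pnext = ((2.0 * n - 1.0) * ue * pn - (n - 1.0) * pm1) / n;
      pm1 = pn;
      pn = pnext;
      S += coef(n, p) * pn;
      tpow *= tp;
      T += tpow * pn;
    }
    const double disc = 1.0 - 2.0 * tp * ue + tp * tp;
    const double g = 1.0 / std::sqrt(disc > 1e-300 ? disc : 1e-300);
    out[e] = S + Ap * (g - T);
  }
  return out;
}
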