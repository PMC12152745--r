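#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive (f, heading) grid search minimizing the airspeed-mixture
// residual |A - f a_b h - (1-f) a_i w| for each input bin. Kept deliberately
// brute-force: this is the independent reference the closed-form quadratic
// solver is validated against.
// [[Rcpp::export]]
NumericMatrix grid_oracle_cpp(NumericVector Au, NumericVector Av,
                              NumericVector wu, NumericVector wv,
                              NumericVector ai, double a_b,
                              double f_step, double theta_step_deg) {
  const int n = Au.size();
  const int nf = (int)std::lround(1.0 / f_step) + 1;
  const int nt = (int)std::lround(360.0 / theta_step_deg);
  std::vector<double> hu(nt), hv(nt);
  for (int j = 0; j < nt; ++j) {
    double th = j * theta_step_deg * M_PI / 180.0;
    hu[j] = std::sin(th);  // compass convention: 0 deg = north
    hv[j] = std::cos(th);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf, bf = NA_REAL, bth = NA_REAL;
    for (int k = 0; k < nf; ++k) {
      double f = k * f_step;
      if (f > 1.0) f = 1.0;
      double ru = Au[i] - (1.0 - f) * ai[i] * wu[i];
      double rv = Av[i] - (1.0 - f) * ai[i] * wv[i];
      double fb = f * a_b;
      if (f == 0.0) {  // no heading term; residual is |A - a_i w|
        double res = std::sqrt(ru * ru + rv * rv);
        if (res < best) { best = res; bf = f; bth = NA_REAL; }
        continue;
      }
      // minimum over theta of |r - fb h| is | |r| - fb |, but scan anyway
      for (int j = 0; j < nt; ++j) {
        double du = ru - fb * hu[j];
        double dv = rv - fb * hv[j];
        double res2 = du * du + dv * dv;
        if (res2 < best * best) {
          best = std::sqrt(res2);
          bf = f;
          bth = j * theta_step_deg;
        }
      }
    }
    out(i, 0) = bf;
    out(i, 1) = bth;
    out(i, 2) = best;
  }
  return out;
}
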