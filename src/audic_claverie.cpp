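#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Audic-Claverie conditional distribution of the second-library count y
// given the first-library count x and the library-size ratio r = N2/N1:
//   p(y | x) = r^y * (x+y)! / (x! y! (1+r)^(x+y+1))
// All tail mass is accumulated in log space (streaming log-sum-exp) so that
// p-values far below double underflow in any single term remain finite.

static double ac_log_cond(double x, double y, double logr, double log1pr) {
  return y * logr + std::lgamma(x + y + 1.0) - std::lgamma(x + 1.0) -
         std::lgamma(y + 1.0) - (x + y + 1.0) * log1pr;
}

static double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a < b ? a : b) - m));
}

// log term recurrence: lp(y+1) = lp(y) + logr - log1pr + log(x+y+1) - log(y+1)

// sum_{y'=0}^{y} p(y'|x)
static double ac_log_lower(double x, double y, double logr, double log1pr) {
  double lp = -(x + 1.0) * log1pr;  // y' = 0
  double ls = lp;
  for (double yy = 0.0; yy < y; yy += 1.0) {
    lp += logr - log1pr + std::log(x + yy + 1.0) - std::log(yy + 1.0);
    ls = logaddexp(ls, lp);
  }
  return ls > 0.0 ? 0.0 : ls;
}

// sum_{y'=y}^{Inf} p(y'|x); terms decay geometrically (ratio < r/(1+r) < 1
// once past the mode), so the sum is truncated when the remainder bound is
// negligible relative to the accumulated mass.
static double ac_log_upper(double x, double y, double logr, double log1pr) {
  if (y <= 0.0) return 0.0;
  double lp = ac_log_cond(x, y, logr, log1pr);
  double ls = lp;
  double yy = y;
  const double lstep = logr - log1pr;  // log(r/(1+r)) < 0
  for (R_xlen_t it = 0; it < 100000000; ++it) {
    double inc = lstep + std::log(x + yy + 1.0) - std::log(yy + 1.0);
    lp += inc;
    yy += 1.0;
    ls = logaddexp(ls, lp);
    if (inc < 0.0) {
      // geometric remainder bound: lp * rho / (1 - rho), rho = exp(inc)
      double lrem = lp + inc - std::log1p(-std::exp(inc));
      if (lrem < ls + std::log(1e-18)) break;
    }
    if (it % 65536 == 65535) Rcpp::checkUserInterrupt();
  }
  return ls > 0.0 ? 0.0 : ls;
}

static double clamp_p(double lp) {
  double p = std::exp(lp);
  if (p <= 0.0) p = DBL_MIN;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".ac_conditional_cpp")]]
NumericVector ac_conditional_cpp(NumericVector x, NumericVector y,
                                 NumericVector N1, NumericVector N2) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = N2[i] / N1[i];
    out[i] = std::exp(ac_log_cond(x[i], y[i], std::log(r), std::log1p(r)));
  }
  return out;
}

// alternative: 1 = up (P[Y >= y]), 2 = down (P[Y <= y]), 3 = two-sided
// [[Rcpp::export(name = ".ac_pvalue_cpp")]]
NumericVector ac_pvalue_cpp(NumericVector x, NumericVector y,
                            NumericVector N1, NumericVector N2,
                            int alternative) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = N2[i] / N1[i];
    double logr = std::log(r), log1pr = std::log1p(r);
    if (alternative == 1) {
      out[i] = clamp_p(ac_log_upper(x[i], y[i], logr, log1pr));
    } else if (alternative == 2) {
      out[i] = clamp_p(ac_log_lower(x[i], y[i], logr, log1pr));
    } else {
      double up = clamp_p(ac_log_upper(x[i], y[i], logr, log1pr));
      double dn = clamp_p(ac_log_lower(x[i], y[i], logr, log1pr));
      double p = 2.0 * (up < dn ? up : dn);
      out[i] = p > 1.0 ? 1.0 : p;
    }
  }
  return out;
}
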