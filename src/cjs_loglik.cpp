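#include <Rcpp.h>
using namespace Rcpp;

// Marginalized Cormack-Jolly-Seber likelihood, forward recursion over the
// latent alive/dead state per individual. Histories are conditioned on the
// individual being alive (and, for conditioned-on-capture data, released)
// at its first occasion; occasions before `first` contribute nothing.
//
// ch:    N x T binary detection matrix (demographic occasions)
// first: length-N first occasion (1-based); individuals with first >= T
//        contribute 0
// phi:   N x (T-1) survival probabilities, phi(i, t) = P(alive at t+1 |
//        alive at t)
// p:     constant detection probability
//
// Returns per-individual log-likelihood contributions.
// [[Rcpp::export]]
NumericVector cjs_loglik_indiv(IntegerMatrix ch, IntegerVector first,
                               NumericMatrix phi, double p) {
  int n = ch.nrow(), T = ch.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int f = first[i];
    if (f >= T) { out[i] = 0.0; continue; }
    // a: P(data so far, alive at t); d: P(data so far, dead at t)
    double a = 1.0, d = 0.0;
    for (int t = f; t < T; ++t) {
      double ph = phi(i, t - 1);
      double anew = a * ph;
      double dnew = d + a * (1.0 - ph);
      if (ch(i, t) == 1) {
        a = anew * p;
        d = 0.0; // detection is impossible while dead
      } else {
        a = anew * (1.0 - p);
        d = dnew;
      }
    }
    double lik = a + d;
    out[i] = (lik > 0.0) ? std::log(lik) : R_NegInf;
  }
  return out;
}

// Same likelihood with the survival linear predictor built in C++:
// phi(i,t) = plogis(b0 + bsex * sex_i + bnet * x(i,t)), avoiding an R-level
// N x (T-1) matrix allocation per MCMC evaluation.
// [[Rcpp::export]]
NumericVector cjs_loglik_reg(IntegerMatrix ch, IntegerVector first,
                             NumericVector sex, NumericMatrix x,
                             double b0, double bsex, double bnet, double p) {
  int n = ch.nrow(), T = ch.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int f = first[i];
    if (f >= T) { out[i] = 0.0; continue; }
    double base = b0 + bsex * sex[i];
    double a = 1.0, d = 0.0;
    for (int t = f; t < T; ++t) {
      double lp = base + bnet * x(i, t - 1);
      double ph = 1.0 / (1.0 + std::exp(-lp));
      double anew = a * ph;
      double dnew = d + a * (1.0 - ph);
      if (ch(i, t) == 1) {
        a = anew * p;
        d = 0.0;
      } else {
        a = anew * (1.0 - p);
        d = dnew;
      }
    }
    double lik = a + d;
    out[i] = (lik > 0.0) ? std::log(lik) : R_NegInf;
  }
  return out;
}
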