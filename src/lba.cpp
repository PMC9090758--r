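#include <RcppArmadillo.h>
#include "lba_kernel.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// R-facing wrappers around the closed-form linear ballistic accumulator
// kernel (see lba_kernel.h): start point ~ Uniform(0, A), drift ~ Normal
// truncated to (0, Inf), threshold b > A.

// [[Rcpp::export]]
NumericVector cpp_acc_cdf(NumericVector t, double A, double b, double v,
                          double sv) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lba::acc_cdf1(t[i], A, b, v, sv);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_acc_pdf(NumericVector t, double A, double b, double v,
                          double sv) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lba::acc_pdf1(t[i], A, b, v, sv);
  return out;
}

// Total log-likelihood of one subject's trials for a block of parameter
// vectors (one per MCMC chain). All condition-indexed parameters arrive
// pre-expanded to 4 columns (shared parameters replicated).
// [[Rcpp::export]]
arma::vec cpp_lba_loglik(const arma::vec &A, const arma::mat &b,
                         const arma::vec &t0, const arma::vec &sv,
                         const arma::mat &vt, const arma::mat &vf,
                         const arma::vec &rt, const arma::ivec &cond,
                         const arma::ivec &correct) {
  int nc = A.n_elem, nt = rt.n_elem;
  arma::vec out(nc);
  for (int c = 0; c < nc; ++c) {
    double brow[4], vtrow[4], vfrow[4];
    for (int k = 0; k < 4; ++k) {
      brow[k] = b(c, k); vtrow[k] = vt(c, k); vfrow[k] = vf(c, k);
    }
    double s = 0.0;
    for (int i = 0; i < nt; ++i)
      s += lba::trial_logdens(rt[i], cond[i], correct[i], A[c], brow, t0[c],
                              sv[c], vtrow, vfrow);
    out[c] = s;
  }
  return out;
}

// Pointwise per-trial log-likelihoods for a block of chains: nc x nt.
// [[Rcpp::export]]
arma::mat cpp_lba_pointwise(const arma::vec &A, const arma::mat &b,
                            const arma::vec &t0, const arma::vec &sv,
                            const arma::mat &vt, const arma::mat &vf,
                            const arma::vec &rt, const arma::ivec &cond,
                            const arma::ivec &correct) {
  int nc = A.n_elem, nt = rt.n_elem;
  arma::mat out(nc, nt);
  for (int c = 0; c < nc; ++c) {
    double brow[4], vtrow[4], vfrow[4];
    for (int k = 0; k < 4; ++k) {
      brow[k] = b(c, k); vtrow[k] = vt(c, k); vfrow[k] = vf(c, k);
    }
    for (int i = 0; i < nt; ++i)
      out(c, i) = lba::trial_logdens(rt[i], cond[i], correct[i], A[c], brow,
                                     t0[c], sv[c], vtrow, vfrow);
  }
  return out;
}
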