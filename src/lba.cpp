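#include <Rcpp.h>
#include "lba.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".lba_cdf_cpp")]]
NumericVector lba_cdf_cpp(NumericVector t, double A, double b, double v, double s) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = lba_cdf1(t[i], A, b, v, s);
  return out;
}

// [[Rcpp::export(name = ".lba_pdf_cpp")]]
NumericVector lba_pdf_cpp(NumericVector t, double A, double b, double v, double s) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = lba_pdf1(t[i], A, b, v, s);
  return out;
}

// [[Rcpp::export(name = ".race_log_density_cpp")]]
NumericVector race_log_density_cpp(NumericVector t, IntegerVector resp,
                                   NumericMatrix drifts, double A, double b,
                                   double s) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  double v[4];
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int r = 0; r < 4; ++r) v[r] = drifts(i % drifts.nrow(), r);
    const double d = lba_race_dens(t[i], resp[i % resp.size()] - 1, v, A, b, s);
    out[i] = d > 0.0 ? std::log(d) : R_NegInf;
  }
  return out;
}

// Summed (and optionally per-row) mixture log likelihood of a trial table.
// theta: n_participants x 17 constrained parameter matrix; pid is 1-based.
// [[Rcpp::export(name = ".dataset_loglik_cpp")]]
List dataset_loglik_cpp(NumericVector rt, IntegerVector resp, IntegerVector mode,
                        IntegerVector kw, IntegerVector kw1c, IntegerVector kw2c,
                        IntegerVector pid, NumericMatrix theta, double lambda,
                        double tmax, bool per_row) {
  const R_xlen_t n = rt.size();
  NumericVector rows(per_row ? n : 0);
  double total = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    // NumericMatrix is column-major: copy the participant row out first.
    double pr[17];
    for (int k = 0; k < 17; ++k) pr[k] = theta(pid[i] - 1, k);
    const double ll = lba_trial_loglik(rt[i], resp[i], mode[i], kw[i],
                                       kw1c[i], kw2c[i], pr, lambda, tmax,
                                       nullptr);
    total += ll;
    if (per_row) rows[i] = ll;
  }
  return List::create(_["total"] = total, _["per_row"] = rows);
}
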