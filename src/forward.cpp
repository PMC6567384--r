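// Scaled forward recursion for the 9-state / 11-event hidden-Markov
// likelihood. Transition slices arrive pre-transposed so each step is a
// plain matrix-vector product; the state space is small and fixed, so the
// recursion uses stack arrays rather than allocating vectors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 9;   // latent states
static const int NE = 11;  // observation codes 0..10

// trans:  9 x 9 x (nAgeClasses * 2), slice k = t(T_k)
// emit:   9 x 11 x nOccasions
// events: n x nOccasions, codes 0..10
// t0, s0: 1-based marking occasion and initial state
// tmIdx:  n x nOccasions, 1-based transition-slice index for the interval
//         ending at each occasion (0 where unused)
// w:      multiplicity weight per (aggregated) history
// logInit: per-history release-occasion contribution
// [[Rcpp::export]]
List cppForwardLogLik(const arma::cube& trans, const arma::cube& emit,
                      const IntegerMatrix& events, const IntegerVector& t0,
                      const IntegerVector& s0, const IntegerMatrix& tmIdx,
                      const NumericVector& w, const NumericVector& logInit) {
  const int n = events.nrow();
  const int nOcc = events.ncol();
  NumericVector ll(n);
  double total = 0.0;
  bool anyBad = false;

  for (int i = 0; i < n; ++i) {
    double a[NS] = {0.0};
    a[s0[i] - 1] = 1.0;
    double lg = logInit[i];
    bool ok = true;
    for (int t = t0[i]; t < nOcc; ++t) {  // 0-based column of occasion t+1
      const double* T = trans.slice_memptr(tmIdx(i, t) - 1);   // 9x9 col-major
      const double* e = emit.slice_memptr(t) + NS * events(i, t);
      double b[NS];
      for (int j = 0; j < NS; ++j) b[j] = 0.0;
      for (int k = 0; k < NS; ++k) {
        const double ak = a[k];
        if (ak == 0.0) continue;
        const double* col = T + NS * k;
        for (int j = 0; j < NS; ++j) b[j] += col[j] * ak;
      }
      double s = 0.0;
      for (int j = 0; j < NS; ++j) { b[j] *= e[j]; s += b[j]; }
      if (!(s > 0.0) || !std::isfinite(s)) { ok = false; break; }
      const double inv = 1.0 / s;
      for (int j = 0; j < NS; ++j) a[j] = b[j] * inv;
      lg += std::log(s);
    }
    if (!ok) { ll[i] = R_NegInf; anyBad = true; }
    else { ll[i] = lg; total += w[i] * lg; }
  }
  if (anyBad) total = R_NegInf;
  return List::create(_["logLik"] = total, _["perHistory"] = ll);
}
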