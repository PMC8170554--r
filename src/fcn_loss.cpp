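// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int wrap(int i, int P) { int r = i % P; return r < 0 ? r + P : r; }

// Scale/shift compensation of all rows of Y and the across-subject variance
// loss it induces.  Row n of C is exp(-s[n]) * Y[n, .] sampled at circularly
// wrapped positions i + d[n] with linear interpolation.  Loss is
//   (1/P) * sum_i var_n(C[, i])  +  gs * mean(s)^2 + gd * mean(d)^2
// with the population (1/n) variance.  Gradients w.r.t. s and d are exact
// almost everywhere (the interpolation is piecewise linear).
// [[Rcpp::export]]
List cpp_scale_shift_loss(const arma::mat& Y, const arma::vec& s,
                          const arma::vec& d, double gs, double gd,
                          bool want_grad, bool want_profiles) {
  const int n = Y.n_rows, P = Y.n_cols;
  arma::mat C(n, P);
  arma::mat slope;           // d C / d position, needed for the d-gradient
  if (want_grad) slope.set_size(n, P);

  for (int r = 0; r < n; ++r) {
    const double es = std::exp(-s[r]);
    const double dr = d[r];
    const int k = (int)std::floor(dr);
    const double f = dr - k;
    for (int i = 0; i < P; ++i) {
      const double y0 = Y(r, wrap(i + k, P));
      const double y1 = Y(r, wrap(i + k + 1, P));
      C(r, i) = es * ((1.0 - f) * y0 + f * y1);
      if (want_grad) slope(r, i) = es * (y1 - y0);
    }
  }

  const arma::rowvec cbar = arma::mean(C, 0);
  arma::mat Cc = C.each_row() - cbar;
  const double ms = arma::mean(s), md = arma::mean(d);
  const double loss = arma::accu(arma::square(Cc)) / ((double)n * P)
    + gs * ms * ms + gd * md * md;

  List out = List::create(Named("loss") = loss);
  if (want_grad) {
    const double w = 2.0 / ((double)n * P);
    arma::vec grad_s = -w * arma::sum(Cc % C, 1) + 2.0 * gs * ms / n;
    arma::vec grad_d =  w * arma::sum(Cc % slope, 1) + 2.0 * gd * md / n;
    out["grad_s"] = grad_s;
    out["grad_d"] = grad_d;
  }
  if (want_profiles) out["profiles"] = C;
  return out;
}
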