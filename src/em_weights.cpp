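// EM for the branch-site class-weight profile: weights carry the
// product structure (qP, (1-q)P, q(1-P), (1-q)(1-P)), making the
// M-step exact. Iterations are O(4S), so running EM to near machine
// tolerance is cheaper than a quasi-Newton step in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::NumericVector cpp_em_weights(const arma::mat& L, const arma::vec& w,
                                   double q, double P, int maxit,
                                   double tol) {
  const arma::uword S = L.n_cols;
  const double eps = 1e-8;
  const double sw = arma::accu(w);
  double lnl = -arma::datum::inf;
  arma::rowvec l1 = L.row(0), l2 = L.row(1), l3 = L.row(2), l4 = L.row(3);
  for (int it = 0; it < maxit; ++it) {
    double r1 = 0.0, r2 = 0.0, r3 = 0.0;
    double newLnl = 0.0;
    const double w11 = q * P, w21 = (1 - q) * P;
    const double w12 = q * (1 - P), w22 = (1 - q) * (1 - P);
    for (arma::uword s = 0; s < S; ++s) {
      const double m1 = w11 * l1(s), m2 = w21 * l2(s);
      const double m3 = w12 * l3(s), m4 = w22 * l4(s);
      const double mix = m1 + m2 + m3 + m4;
      if (mix <= 0.0)
        return Rcpp::NumericVector::create(q, P, -arma::datum::inf);
      const double wm = w(s) / mix;
      newLnl += w(s) * std::log(mix);
      r1 += m1 * wm; r2 += m2 * wm; r3 += m3 * wm;
    }
    q = std::min(std::max((r1 + r3) / sw, eps), 1 - eps);
    P = std::min(std::max((r1 + r2) / sw, eps), 1 - eps);
    if (newLnl - lnl < tol && it > 2) { lnl = newLnl; break; }
    lnl = newLnl;
  }
  return Rcpp::NumericVector::create(q, P, lnl);
}
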