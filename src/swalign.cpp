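// Affine-gap local alignment (Smith-Waterman) score on integer-encoded
// peptides; a gap of length k costs gapOpen + k * gapExt, matching the
// package's translated-similarity conventions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// As cpp_sw_score but also reports the 1-based end positions of the best
// local alignment in both sequences (first maximum in row-major scan).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_sw_ends(const arma::ivec& a, const arma::ivec& b,
                                const arma::mat& S, double gapOpen,
                                double gapExt) {
  const arma::uword n = a.n_elem, m = b.n_elem;
  double best = 0.0;
  arma::uword bi = 0, bj = 0;
  if (n > 0 && m > 0) {
    arma::vec H(m + 1, arma::fill::zeros), E(m + 1);
    E.fill(-1e18);
    const double go = gapOpen + gapExt;
    for (arma::uword i = 1; i <= n; ++i) {
      double diag = 0.0, F = -1e18, Hij0 = 0.0;
      for (arma::uword j = 1; j <= m; ++j) {
        E(j) = std::max(H(j) - go, E(j) - gapExt);
        F = std::max(Hij0 - go, F - gapExt);
        double h = diag + S(a(i - 1), b(j - 1));
        h = std::max(std::max(h, E(j)), std::max(F, 0.0));
        diag = H(j);
        H(j) = h;
        Hij0 = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
  }
  return Rcpp::NumericVector::create(best, (double)bi, (double)bj);
}

// [[Rcpp::export]]
double cpp_sw_score(const arma::ivec& a, const arma::ivec& b,
                    const arma::mat& S, double gapOpen, double gapExt) {
  const arma::uword n = a.n_elem, m = b.n_elem;
  if (n == 0 || m == 0) return 0.0;
  arma::vec H(m + 1, arma::fill::zeros), E(m + 1);
  E.fill(-1e18);
  double best = 0.0;
  const double go = gapOpen + gapExt;
  for (arma::uword i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][0]
    double F = -1e18;
    double Hij0 = 0.0;       // H[i][0]
    for (arma::uword j = 1; j <= m; ++j) {
      E(j) = std::max(H(j) - go, E(j) - gapExt);
      F = std::max(Hij0 - go, F - gapExt);
      double h = diag + S(a(i - 1), b(j - 1));
      h = std::max(h, E(j));
      h = std::max(h, F);
      h = std::max(h, 0.0);
      diag = H(j);
      H(j) = h;
      Hij0 = h;
      if (h > best) best = h;
    }
    H(0) = 0.0;
  }
  return best;
}
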