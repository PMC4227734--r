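// Likelihood engine for time-reversible substitution models on fixed
// topologies: eigendecomposition of GTR-form generators, transition
// matrices, and Felsenstein pruning over compressed site patterns.
// State space is generic (4 for nucleotides, 61 for sense codons).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Eigendecomposition of the reversible generator Q_ij = M_ij * pi_j
// (i != j), diagonal set so rows sum to zero, scaled so the expected
// substitution rate at stationarity -sum_i pi_i Q_ii equals 1.
// M must be symmetric with zeros on forbidden changes. Returns the
// factors of P(t) = W1 diag(exp(lambda t)) W2 where W1 = D^{-1/2} V,
// W2 = V' D^{1/2}, B = D^{1/2} Q D^{-1/2} = V diag(lambda) V'.
// [[Rcpp::export]]
Rcpp::List cpp_rev_eig(const arma::mat& M, const arma::vec& pi) {
  mat Q = M;
  Q.each_row() %= pi.t();          // Q_ij = M_ij * pi_j
  Q.diag().zeros();
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  double scale = dot(pi, rs);      // expected flux at stationarity
  if (scale <= 0.0) Rcpp::stop("degenerate rate matrix: zero total flux");
  Q /= scale;
  vec sp = sqrt(pi);
  mat B = Q;
  B.each_col() %= sp;              // B_ij = sp_i * Q_ij / sp_j
  B.each_row() /= sp.t();
  B = 0.5 * (B + B.t());           // symmetrize against round-off
  vec lam;
  mat V;
  if (!eig_sym(lam, V, B)) Rcpp::stop("eigendecomposition failed");
  mat W1 = V;
  W1.each_col() /= sp;
  mat W2 = V.t();
  W2.each_row() %= sp.t();
  return Rcpp::List::create(Rcpp::Named("lambda") = lam,
                            Rcpp::Named("W1") = W1,
                            Rcpp::Named("W2") = W2,
                            Rcpp::Named("scale") = scale);
}

// P(t) = W1 diag(exp(lambda t)) W2, clamped to [0, 1] elementwise
// (round-off can produce tiny negatives for near-zero entries).
// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::vec& lambda, const arma::mat& W1,
                   const arma::mat& W2, double t) {
  if (t < 0) Rcpp::stop("negative branch length");
  mat P = W1 * diagmat(exp(lambda * t)) * W2;
  P.clamp(0.0, 1.0);
  return P;
}

// Postorder pruning pass. states: ntaxa x S integer matrix of 1-based
// state indices, 0 meaning missing (gap/ambiguity, marginalized).
// edge: nedges x 2 (parent, child), 1-based node ids with tips 1..ntaxa,
// ordered so every child's subtree precedes its edge. Pcube: one
// transition matrix per edge. Returns the per-node partial likelihoods
// ("Lnode", nstates x S x nnodes) and the per-edge lifted child
// partials ("lifted", P_e %*% Lnode[child]).
// [[Rcpp::export]]
Rcpp::List cpp_prune(const arma::imat& states, const arma::imat& edge,
                     const arma::cube& Pcube, int nnodes) {
  const uword ntaxa = states.n_rows;
  const uword S = states.n_cols;
  const uword ns = Pcube.n_rows;
  const uword ne = edge.n_rows;
  cube Lnode(ns, S, (uword)nnodes, fill::ones);
  for (uword tx = 0; tx < ntaxa; ++tx) {
    for (uword s = 0; s < S; ++s) {
      int st = states(tx, s);
      if (st > 0) {
        Lnode.slice(tx).col(s).zeros();
        Lnode(st - 1, s, tx) = 1.0;
      } // st == 0: all-ones column (missing data)
    }
  }
  cube lifted(ns, S, ne);
  for (uword e = 0; e < ne; ++e) {
    int par = edge(e, 0), chl = edge(e, 1);
    lifted.slice(e) = Pcube.slice(e) * Lnode.slice(chl - 1);
    Lnode.slice(par - 1) %= lifted.slice(e);
  }
  return Rcpp::List::create(Rcpp::Named("Lnode") = Lnode,
                            Rcpp::Named("lifted") = lifted);
}

// Transition matrices for many branch lengths at once.
// [[Rcpp::export]]
arma::cube cpp_pmat_cube(const arma::vec& lambda, const arma::mat& W1,
                         const arma::mat& W2, const arma::vec& ts) {
  const uword n = lambda.n_elem;
  cube out(n, n, ts.n_elem);
  for (uword e = 0; e < ts.n_elem; ++e) {
    if (ts(e) < 0) Rcpp::stop("negative branch length");
    mat P = W1 * diagmat(exp(lambda * ts(e))) * W2;
    P.clamp(0.0, 1.0);
    out.slice(e) = P;
  }
  return out;
}

// Pruning pass returning only the two conditionals either side of one
// root-adjacent edge 'exclEdge' (1-based row of 'edge', whose parent must
// be the root): A = product of the other root edges' lifted partials,
// B = the partial at the excluded edge's child.
// [[Rcpp::export]]
Rcpp::List cpp_halves(const arma::imat& states, const arma::imat& edge,
                      const arma::cube& Pcube, int nnodes, int root,
                      int exclEdge) {
  const uword ntaxa = states.n_rows;
  const uword S = states.n_cols;
  const uword ns = Pcube.n_rows;
  const uword ne = edge.n_rows;
  cube Lnode(ns, S, (uword)nnodes, fill::ones);
  for (uword tx = 0; tx < ntaxa; ++tx) {
    for (uword s = 0; s < S; ++s) {
      int st = states(tx, s);
      if (st > 0) {
        Lnode.slice(tx).col(s).zeros();
        Lnode(st - 1, s, tx) = 1.0;
      }
    }
  }
  mat A(ns, S, fill::ones);
  for (uword e = 0; e < ne; ++e) {
    int par = edge(e, 0), chl = edge(e, 1);
    if ((int)e + 1 == exclEdge) continue;  // leave this edge out entirely
    mat lifted = Pcube.slice(e) * Lnode.slice(chl - 1);
    if (par == root) A %= lifted;
    else Lnode.slice(par - 1) %= lifted;
  }
  mat B = Lnode.slice(edge(exclEdge - 1, 1) - 1);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("B") = B);
}

// Full pruning pass returning the per-pattern site likelihoods at the
// root (no intermediate cubes cross the R boundary).
// [[Rcpp::export]]
arma::rowvec cpp_sitelik(const arma::imat& states, const arma::imat& edge,
                         const arma::cube& Pcube, int nnodes, int root,
                         const arma::vec& pi) {
  const uword ntaxa = states.n_rows;
  const uword S = states.n_cols;
  const uword ns = Pcube.n_rows;
  const uword ne = edge.n_rows;
  cube Lnode(ns, S, (uword)nnodes, fill::ones);
  for (uword tx = 0; tx < ntaxa; ++tx) {
    for (uword s = 0; s < S; ++s) {
      int st = states(tx, s);
      if (st > 0) {
        Lnode.slice(tx).col(s).zeros();
        Lnode(st - 1, s, tx) = 1.0;
      }
    }
  }
  for (uword e = 0; e < ne; ++e) {
    int par = edge(e, 0), chl = edge(e, 1);
    Lnode.slice(par - 1) %= Pcube.slice(e) * Lnode.slice(chl - 1);
  }
  mat tmp = Lnode.slice(root - 1);
  tmp.each_col() %= pi;
  return sum(tmp, 0);
}

// Per-pattern site likelihood across one edge splitting the tree into
// halves with conditionals A (at the parent side) and B (child side):
// l(s) = sum_i pi_i A_is (P B)_is.
// [[Rcpp::export]]
arma::rowvec cpp_edge_sitelik(const arma::mat& A, const arma::mat& B,
                              const arma::mat& P, const arma::vec& pi) {
  mat PB = P * B;
  mat tmp = A % PB;
  tmp.each_col() %= pi;
  return sum(tmp, 0);
}

// Root-level per-pattern site likelihoods: l(s) = sum_i pi_i L_is.
// [[Rcpp::export]]
arma::rowvec cpp_root_sitelik(const arma::mat& Lroot, const arma::vec& pi) {
  mat tmp = Lroot;
  tmp.each_col() %= pi;
  return sum(tmp, 0);
}
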