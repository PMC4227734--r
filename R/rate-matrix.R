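#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 generator of the codon substitution process. Off-
#' diagonal entries for codons differing at exactly one nucleotide are
#' proportional to \code{pi[j]} times 1 (synonymous transversion),
#' \code{kappa} (synonymous transition), \code{omega} (nonsynonymous
#' transversion) or \code{omega * kappa} (nonsynonymous transition); all
#' multi-step changes and changes through stop codons are forbidden. The
#' diagonal makes rows sum to zero and the matrix is scaled so the expected
#' number of substitutions per codon per unit branch length at stationarity
#' is exactly 1.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio, >= 0.
#' @param pi codon frequency vector over the 61 sense codons (sums to 1).
#' @return a 61 x 61 matrix with rows summing to 0.
#' @examples
#' Q <- codonRateMatrix(kappa = 2, omega = 0.5)
#' max(abs(rowSums(Q)))  # ~0
#' @export
codonRateMatrix <- function(kappa, omega, pi = equalCodonFrequencies()) {
  M <- .codonRelRates(kappa, omega)
  pi <- .checkCodonFrequencies(pi)
  Q <- M * rep(pi, each = nrow(M))
  diag(Q) <- 0
  rs <- rowSums(Q)
  diag(Q) <- -rs
  Q / sum(pi * rs)
}

# Symmetric relative-rate factor matrix: M_ij such that q_ij = M_ij * pi_j.
.codonRelRates <- function(kappa, omega) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  types <- .codonPairTypes()
  mult <- c(1, kappa, omega, omega * kappa)
  M <- matrix(0, nrow(types), ncol(types), dimnames = dimnames(types))
  nz <- types != 0L
  M[nz] <- mult[types[nz]]
  M
}

# Eigendecomposition wrapper; elements lambda/W1/W2 feed transitionMatrix().
.codonEigen <- function(kappa, omega, pi) {
  pi <- .checkCodonFrequencies(pi)
  cpp_rev_eig(.codonRelRates(kappa, omega), pi)
}

.gtrEigen <- function(rates, pi) {
  # rates: 6 exchangeabilities in order AC, AG, AT, CG, CT, GT
  stopifnot(length(rates) == 6, all(rates > 0), length(pi) == 4)
  M <- matrix(0, 4, 4, dimnames = list(.NUC, .NUC))
  M[lower.tri(M)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # lower.tri order: (C,A),(G,A),(T,A),(G,C),(T,C),(T,G) = AC,AG,AT,CG,CT,GT
  M <- M + t(M)
  cpp_rev_eig(M, pi / sum(pi))
}

#' Transition probability matrix P(t) = expm(Q t)
#'
#' Computed from the cached eigendecomposition of the reversible generator;
#' rows sum to 1 and \code{P(0)} is the identity.
#'
#' @param eig an eigendecomposition as returned internally by the model
#'   builders, or a rate matrix parameter list with \code{kappa},
#'   \code{omega}, \code{pi}.
#' @param t branch length, >= 0, in expected substitutions per site.
#' @return stochastic matrix of transition probabilities.
#' @export
transitionMatrix <- function(eig, t) {
  if (is.numeric(t) && length(t) == 1 && t < 0) stop("negative branch length")
  if (!is.list(eig) || is.null(eig$lambda)) {
    eig <- .codonEigen(eig$kappa, eig$omega, eig$pi)
  }
  cpp_pmat(eig$lambda, eig$W1, eig$W2, t)
}

# Raw stationary flux of the unscaled generator, split into its
# synonymous and nonsynonymous parts: flux(omega) = fs + omega * fn.
# Site-class mixtures share a common scale, so a class's substitution
# rate relative to a neutral site is (fs + omega*fn) / (fs + fn).
.fluxParts <- function(kappa, pi) {
  pi <- .checkCodonFrequencies(pi)
  types <- .codonPairTypes()
  Msyn <- matrix(0, nrow(types), ncol(types))
  Msyn[types == 1L] <- 1
  Msyn[types == 2L] <- kappa
  Mnon <- matrix(0, nrow(types), ncol(types))
  Mnon[types == 3L] <- 1
  Mnon[types == 4L] <- kappa
  c(fs = as.numeric(pi %*% Msyn %*% pi), fn = as.numeric(pi %*% Mnon %*% pi))
}

# Proportions of the stationary substitution flux that are synonymous /
# nonsynonymous under (kappa, omega, pi). With the generator scaled to unit
# total flux these are the expected fractions of substitutions of each kind.
.fluxProportions <- function(kappa, omega, pi) {
  pi <- .checkCodonFrequencies(pi)
  types <- .codonPairTypes()
  M <- .codonRelRates(kappa, omega)
  Q <- M * rep(pi, each = nrow(M))
  flux <- pi * Q  # pi_i q_ij elementwise by row
  tot <- sum(flux)
  syn <- sum(flux[types == 1L | types == 2L])
  c(syn = syn / tot, nonsyn = 1 - syn / tot)
}

#' Synonymous and nonsynonymous site proportions of the codon process
#'
#' The mutational-opportunity convention: site proportions are the
#' stationary substitution flux fractions of the process with \code{omega}
#' forced to 1, so selection does not alter what counts as a synonymous
#' "site". Used to convert fitted branch lengths and omegas into Ka and Ks.
#'
#' @inheritParams codonRateMatrix
#' @return named vector \code{c(syn=, nonsyn=)} summing to 1.
#' @export
siteProportions <- function(kappa, pi = equalCodonFrequencies()) {
  .fluxProportions(kappa, 1, pi)
}
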