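# Reference likelihood path: per-class full pruning passes. The model
# fitting routines use a cached decomposition across the foreground edge
# instead; this function is the plain, easily-audited route used by the
# simulator tests and exported for direct likelihood evaluation.

.buildPcube <- function(eig, lens) {
  cpp_pmat_cube(eig$lambda, eig$W1, eig$W2, lens)
}

.sumLogLik <- function(sitelik, weights) {
  if (any(sitelik <= 0)) return(-Inf)
  sum(weights * log(sitelik))
}

# Prune the tree down to the alignment's taxa (error if the alignment has
# taxa the tree lacks) and return the working phylo + foreground edge row.
.fitContext <- function(alignment, tree, pi = "f3x4") {
  stree <- if (methods::is(tree, "SpeciesTree")) tree else SpeciesTree(tree)
  phy <- stree@tree
  taxaAln <- taxa(alignment)
  extra <- setdiff(taxaAln, phy$tip.label)
  if (length(extra))
    stop(sprintf("alignment taxa not in tree: %s", paste(extra, collapse = ", ")))
  if (length(setdiff(phy$tip.label, taxaAln))) {
    phy <- ape::keep.tip(phy, taxaAln)
    stree <- SpeciesTree(phy, stree@foreground)
  }
  piVec <- if (is.character(pi)) {
    switch(match.arg(pi, c("f3x4", "equal")),
           f3x4 = f3x4Frequencies(alignment),
           equal = equalCodonFrequencies())
  } else .checkCodonFrequencies(pi)
  pat <- .alignmentPatterns(alignment, phy$tip.label)
  list(stree = stree, phy = phy, pi = piVec,
       states = pat$states, weights = pat$weights)
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over the 61 sense-codon states, mixed over site
#' classes. Each site class has a background omega (all branches) and a
#' foreground omega (the tree's flagged branch); a single-class call with
#' \code{background == foreground} is the one-ratio model. Gap and
#' ambiguous codons are treated as missing data and marginalized. Because
#' the process is reversible the value does not depend on where the
#' unrooted tree is rooted.
#'
#' @param alignment a \linkS4class{CodonAlignment}.
#' @param tree a \linkS4class{SpeciesTree} (foreground mark required only
#'   when a class distinguishes foreground from background).
#' @param kappa transition/transversion rate ratio.
#' @param omega single omega for the one-class model (ignored when
#'   \code{classes} is given).
#' @param classes optional data.frame with columns \code{proportion},
#'   \code{background}, \code{foreground} (omegas per site class).
#' @param pi \code{"f3x4"} (default), \code{"equal"}, or a 61-vector.
#' @details Site classes share one scale factor: branch lengths are in
#'   expected substitutions per codon for a site drawn from the class
#'   mixture on a background branch, so classes with larger omega evolve
#'   proportionally faster instead of being renormalized per class.
#' @return the log-likelihood (scalar).
#' @export
codonLogLik <- function(alignment, tree, kappa = 2, omega = 0.3,
                        classes = NULL, pi = "f3x4") {
  ctx <- .fitContext(alignment, tree, pi)
  if (is.null(classes))
    classes <- data.frame(proportion = 1, background = omega,
                          foreground = omega)
  if (abs(sum(classes$proportion) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  needsFg <- any(classes$background != classes$foreground)
  phy <- ctx$phy
  if (needsFg) {
    fgRow <- .foregroundEdgeRow(ctx$stree)
    eng <- .treeEngine(phy, root = phy$edge[fgRow, 1])
  } else {
    fgRow <- 0L
    eng <- .treeEngine(phy)
  }
  fgIdx <- if (fgRow > 0L) which(eng$orig == fgRow) else 0L
  fp <- .fluxParts(kappa, ctx$pi)
  sW <- function(w) fp["fs"] + w * fp["fn"]
  sBar <- sum(classes$proportion * sW(classes$background))
  mix <- numeric(length(ctx$weights))
  for (cl in seq_len(nrow(classes))) {
    wBg <- classes$background[cl]
    eigBg <- .codonEigen(kappa, wBg, ctx$pi)
    Pcube <- .buildPcube(eigBg, eng$len * sW(wBg) / sBar)
    if (fgIdx > 0L && classes$foreground[cl] != wBg) {
      wFg <- classes$foreground[cl]
      eigFg <- .codonEigen(kappa, wFg, ctx$pi)
      Pcube[, , fgIdx] <- cpp_pmat(eigFg$lambda, eigFg$W1, eigFg$W2,
                                   eng$len[fgIdx] * sW(wFg) / sBar)
    }
    sl <- as.vector(cpp_sitelik(ctx$states, eng$edge, Pcube, eng$nnodes,
                                eng$root, ctx$pi))
    mix <- mix + classes$proportion[cl] * sl
  }
  .sumLogLik(mix, ctx$weights)
}

# One pruning pass rooted at 'eng$root'; returns the "outside" conditional
# A at the root excluding the edge 'exclIdx', and the subtree conditional
# B below that edge. Both sides then meet across the excluded edge via
# cpp_edge_sitelik.
.halfConditionals <- function(eng, states, Pcube, exclIdx) {
  cpp_halves(states, eng$edge, Pcube, eng$nnodes, eng$root, exclIdx)
}
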