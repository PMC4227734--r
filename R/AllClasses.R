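#' @importClassesFrom Biostrings DNAStringSet
NULL

setOldClass("phylo")

#' CodonAlignment: an in-frame aligned set of coding sequences
#'
#' Holds one ortholog family's aligned codon sequences as a
#' \linkS4class{DNAStringSet} of equal width. Every sequence length is a
#' multiple of 3 and every codon is either gap-free or the all-gap codon
#' \code{"---"}; partially gapped codons are invalid.
#'
#' @slot aln a \code{Biostrings::DNAStringSet}, one sequence per taxon.
#' @slot geneId single gene identifier.
#' @export
setClass("CodonAlignment",
         representation(aln = "DNAStringSet", geneId = "character"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(w) == 0L) return(TRUE)
  if (length(unique(w)) != 1L) return("all sequences must have equal length")
  if (w[1] %% 3 != 0) return("alignment length must be a multiple of 3")
  if (length(object@geneId) != 1L) return("geneId must be a single string")
  m <- codonMatrix(object, validate = FALSE)
  ngap <- nchar(gsub("[^-]", "", m))
  if (any(ngap %in% c(1L, 2L)))
    return("partially gapped codon found; codons must be all-gap or gap-free")
  TRUE
})

#' @describeIn CodonAlignment construct from a DNAStringSet, a named
#'   character vector of sequences, or a character matrix of codons.
#' @param x sequences (see above).
#' @param geneId gene identifier.
#' @export
CodonAlignment <- function(x, geneId = "gene") {
  if (is.matrix(x)) {
    seqs <- apply(x, 1, paste0, collapse = "")
    x <- Biostrings::DNAStringSet(seqs)
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  methods::new("CodonAlignment", aln = x, geneId = as.character(geneId))
}

#' SpeciesTree: fixed topology with branch lengths and a foreground branch
#'
#' Wraps an \code{ape} \code{phylo} tree (stored with a trifurcating root
#' for unrooted use) together with the label of the taxon or internal node
#' whose parent edge is the designated foreground branch for branch-site
#' fits. The default study topology is the five-taxon tree
#' \code{(((vlangalii, przewalskii), anolis), gallus, pelodiscus)} with the
#' high-elevation lineage as foreground.
#'
#' @slot tree a \code{phylo} object with branch lengths.
#' @slot foreground label of the node whose parent edge is foreground
#'   (\code{NA_character_} if no branch is flagged).
#' @export
setClass("SpeciesTree",
         representation(tree = "phylo", foreground = "character"))

setValidity("SpeciesTree", function(object) {
  phy <- object@tree
  if (is.null(phy$edge.length)) return("tree must have branch lengths")
  if (any(phy$edge.length < 0)) return("negative branch length")
  if (length(object@foreground) != 1L) return("exactly one foreground slot")
  fg <- object@foreground
  if (!is.na(fg) && !(fg %in% c(phy$tip.label, phy$node.label)))
    return(sprintf("foreground label '%s' not found in tree", fg))
  TRUE
})

#' @describeIn SpeciesTree construct from a phylo object.
#' @param tree a \code{phylo}.
#' @param foreground node label (usually a tip) of the foreground branch.
#' @export
SpeciesTree <- function(tree, foreground = NA_character_) {
  methods::new("SpeciesTree", tree = tree,
               foreground = as.character(foreground))
}

#' BranchSiteFit: result of the branch-site likelihood-ratio test
#'
#' Stores the maximized log-likelihoods of branch-site model A (foreground
#' omega2 free, >= 1) and its null (omega2 fixed at 1), the LRT statistic
#' 2*(lnL_alt - lnL_null) clamped at zero, its chi-square (df = 1) p-value,
#' and the fitted site-class parameters.
#'
#' @slot geneId gene identifier.
#' @slot lnLAlt,lnLNull maximized log-likelihoods.
#' @slot lrt LRT statistic, >= 0.
#' @slot pValue upper-tail chi-square(1) p-value.
#' @slot kappa fitted transition/transversion ratio (shared by both models).
#' @slot p0,p1 fitted proportions of site classes 0 and 1 (alternative fit).
#' @slot omega0 fitted background purifying omega, in (0, 1).
#' @slot omega2 fitted foreground omega, >= 1 (1 in the null).
#' @slot diagnostics list of optimizer details (starts, convergence,
#'   reliability flag).
#' @export
setClass("BranchSiteFit",
         representation(geneId = "character", lnLAlt = "numeric",
                        lnLNull = "numeric", lrt = "numeric",
                        pValue = "numeric", kappa = "numeric",
                        p0 = "numeric", p1 = "numeric", omega0 = "numeric",
                        omega2 = "numeric", diagnostics = "list"))

setValidity("BranchSiteFit", function(object) {
  if (object@lrt < 0) return("lrt must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("pValue out of [0,1]")
  if (object@p0 + object@p1 > 1 + 1e-8) return("p0 + p1 must be <= 1")
  TRUE
})

#' BranchRates: per-branch rates from the free-ratio model
#'
#' One row per branch of the fitted tree with the branch length \code{t}
#' (expected substitutions per codon), the branch omega, Ka and Ks
#' (substitutions per nonsynonymous / synonymous site), and the expected
#' substitution counts \code{nhat}, \code{shat} over the whole gene.
#' Branches with zero length report \code{omega = NA} and zero rates.
#'
#' @slot geneId gene identifier.
#' @slot kappa fitted shared kappa.
#' @slot lnL maximized log-likelihood.
#' @slot table data.frame with columns \code{branch}, \code{t},
#'   \code{omega}, \code{Ka}, \code{Ks}, \code{nhat}, \code{shat}.
#' @export
setClass("BranchRates",
         representation(geneId = "character", kappa = "numeric",
                        lnL = "numeric", table = "data.frame"))

setValidity("BranchRates", function(object) {
  tb <- object@table
  need <- c("branch", "t", "omega", "Ka", "Ks", "nhat", "shat")
  if (!all(need %in% names(tb))) return("missing BranchRates columns")
  if (any(tb$Ka < 0, na.rm = TRUE) || any(tb$Ks < 0, na.rm = TRUE))
    return("Ka and Ks must be >= 0")
  TRUE
})
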