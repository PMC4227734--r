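#' Accessors for CodonScan classes
#'
#' Small generic accessors: \code{geneId} returns the gene identifier,
#' \code{taxa} the taxon labels, \code{numCodons} the alignment length in
#' codons, \code{pValue} and \code{lrtStatistic} the test result of a
#' \linkS4class{BranchSiteFit}, \code{branchRates} the per-branch table of
#' a \linkS4class{BranchRates}, and \code{foregroundTaxon} the foreground
#' label of a \linkS4class{SpeciesTree}.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("numCodons", function(x) standardGeneric("numCodons"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("lrtStatistic", function(x) standardGeneric("lrtStatistic"))
#' @rdname accessors
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))
#' @rdname accessors
#' @export
setGeneric("foregroundTaxon", function(x) standardGeneric("foregroundTaxon"))

#' @rdname accessors
#' @export
setMethod("geneId", "CodonAlignment", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "BranchSiteFit", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "BranchRates", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("taxa", "CodonAlignment", function(x) names(x@aln))
#' @rdname accessors
#' @export
setMethod("taxa", "SpeciesTree", function(x) x@tree$tip.label)
#' @rdname accessors
#' @export
setMethod("numCodons", "CodonAlignment", function(x) {
  if (length(x@aln) == 0L) return(0L)
  as.integer(Biostrings::width(x@aln)[1] %/% 3)
})
#' @rdname accessors
#' @export
setMethod("pValue", "BranchSiteFit", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("lrtStatistic", "BranchSiteFit", function(x) x@lrt)
#' @rdname accessors
#' @export
setMethod("branchRates", "BranchRates", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("foregroundTaxon", "SpeciesTree", function(x) x@foreground)

#' @describeIn accessors PSG call at level \code{alpha}: p-value strictly
#'   below the threshold and a reliable fit.
#' @param alpha significance level for the PSG call.
#' @export
isPSG <- function(x, alpha = 0.05) {
  stopifnot(methods::is(x, "BranchSiteFit"))
  ok <- !isTRUE(x@diagnostics$unreliable)
  ok && x@pValue < alpha
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment '%s': %d taxa x %d codons\n",
              object@geneId, length(object@aln), numCodons(object)))
})

setMethod("show", "SpeciesTree", function(object) {
  fg <- if (is.na(object@foreground)) "none" else object@foreground
  cat(sprintf("SpeciesTree: %d tips, foreground branch: %s\n",
              length(object@tree$tip.label), fg))
})

setMethod("show", "BranchSiteFit", function(object) {
  cat(sprintf(
    "BranchSiteFit '%s'\n  lnL alt/null: %.4f / %.4f\n  2*dlnL = %.4f, p = %.4g\n  omega0 = %.3f, omega2 = %.3f, p0 = %.3f, p1 = %.3f\n",
    object@geneId, object@lnLAlt, object@lnLNull, object@lrt,
    object@pValue, object@omega0, object@omega2, object@p0, object@p1))
})

setMethod("show", "BranchRates", function(object) {
  cat(sprintf("BranchRates '%s' (kappa = %.3f, lnL = %.3f)\n",
              object@geneId, object@kappa, object@lnL))
  print(object@table, digits = 4)
})
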