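#' Consensus base calls from per-site read-support counts
#'
#' For each site the base with the most mapped reads is chosen; sites with
#' no support at all return \code{N}. Ties break alphabetically
#' (A < C < G < T), a deterministic documented rule.
#'
#' @param counts matrix (sites x 4, columns A, C, G, T) or a single named
#'   count vector.
#' @return character vector of consensus bases.
#' @examples
#' consensusCall(c(A = 10, G = 3))  # "A"
#' consensusCall(c(A = 5, T = 5))   # "A" (alphabetical tie rule)
#' @export
consensusCall <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- .NUC
  counts <- counts[, .NUC, drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  apply(counts, 1, function(x) {
    if (all(x == 0)) return("N")
    .NUC[which.max(x)]  # which.max takes the first (alphabetical) maximum
  })
}

#' Trim a codon alignment to reliable blocks
#'
#' A simplified block filter in the spirit of codon-mode alignment
#' trimmers: a codon column is "good" when its gap fraction is at most
#' \code{maxGapFraction} and at least half of the taxa share the majority
#' amino acid; maximal runs of at least \code{minBlock} consecutive good
#' columns are kept and concatenated in order. Everything else is removed.
#'
#' @param alignment a \linkS4class{CodonAlignment}.
#' @param minBlock minimum kept block length in codons.
#' @param maxGapFraction maximum per-column fraction of gap codons.
#' @return the trimmed \linkS4class{CodonAlignment} (possibly empty).
#' @export
trimAlignmentBlocks <- function(alignment, minBlock = 5,
                                maxGapFraction = 0) {
  m <- codonMatrix(alignment)
  if (ncol(m) == 0L) return(alignment)
  ntaxa <- nrow(m)
  aa <- codonTable()
  good <- vapply(seq_len(ncol(m)), function(j) {
    col <- toupper(m[, j])
    isGap <- col == "---"
    if (mean(isGap) > maxGapFraction) return(FALSE)
    res <- aa[col[!isGap]]
    res[is.na(res)] <- "X"
    tab <- table(res)
    max(tab) >= ntaxa / 2
  }, logical(1))
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keepCols <- integer(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= minBlock)
      keepCols <- c(keepCols, starts[i]:ends[i])
  }
  kept <- m[, keepCols, drop = FALSE]
  seqs <- if (ncol(kept) == 0L) {
    stats::setNames(rep("", nrow(m)), rownames(m))
  } else {
    apply(kept, 1, paste0, collapse = "")
  }
  CodonAlignment(Biostrings::DNAStringSet(seqs), geneId = geneId(alignment))
}

#' Length and stop-codon filter for ortholog alignments
#'
#' A gene is kept iff no sequence contains a stop codon and the (trimmed)
#' alignment length is at least \code{minLengthBp} nucleotides; the
#' boundary is kept at exactly \code{minLengthBp}. Rejections are logged
#' with a reason.
#'
#' @param alignments list of \linkS4class{CodonAlignment}s.
#' @param minLengthBp minimum alignment length in bp (default 200).
#' @return list with \code{kept} (named list of alignments) and
#'   \code{log} (data.frame gene_id, kept, reason).
#' @export
filterOrthologs <- function(alignments, minLengthBp = 200) {
  stopsSet <- stopCodons()
  kept <- list()
  logRows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    lenBp <- 3 * numCodons(a)
    reason <- ""
    if (any(toupper(codonMatrix(a)) %in% stopsSet)) {
      reason <- "stop_codon"
    } else if (lenBp < minLengthBp) {
      reason <- "too_short"
    }
    if (reason == "") kept[[geneId(a)]] <- a
    logRows[[i]] <- data.frame(gene_id = geneId(a), kept = reason == "",
                               reason = ifelse(reason == "", "pass", reason),
                               length_bp = lenBp, stringsAsFactors = FALSE)
  }
  logDf <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(gene_id = character(0), kept = logical(0),
               reason = character(0), length_bp = numeric(0))
  list(kept = kept, log = logDf)
}

# ML fit of GTR branch lengths on nucleotide site patterns with the
# topology fixed. Exchangeabilities (GT fixed at 1) and branch lengths are
# jointly optimized by bounded quasi-Newton from 3 deterministic starts;
# base frequencies are empirical.
.fitGtrBranchLengths <- function(chars, phy, starts = 3) {
  taxaOrder <- phy$tip.label
  pat <- .nucPatterns(chars, taxaOrder)
  counts <- table(factor(toupper(chars)[toupper(chars) %in% .NUC],
                         levels = .NUC))
  freqs <- (as.numeric(counts) + 0.5) / sum(as.numeric(counts) + 0.5)
  eng <- .treeEngine(phy)
  ne <- nrow(phy$edge)
  varSites <- any(apply(pat$states, 2, function(s) {
    s <- s[s > 0]; length(unique(s)) > 1
  }))
  if (!varSites) {
    return(list(blens = stats::setNames(rep(0, ne), .edgeLabels(phy)),
                converged = TRUE, lnL = 0, rates = rep(1, 6)))
  }
  nll <- function(par) {
    lens <- exp(par[seq_len(ne)])
    rates <- c(exp(par[ne + 1:5]), 1)
    eig <- .gtrEigen(rates, freqs)
    Pcube <- .buildPcube(eig, lens[eng$orig])
    pr <- cpp_prune(pat$states, eng$edge, Pcube, eng$nnodes)
    sl <- as.vector(cpp_root_sitelik(pr$Lnode[, , eng$root], freqs))
    -.sumLogLik(sl, pat$weights)
  }
  inits <- list(c(rep(0.2, ne), rep(1, 5)),
                c(rep(0.05, ne), c(1, 3, 1, 1, 3)),
                c(rep(0.8, ne), rep(1, 5)))[seq_len(starts)]
  best <- NULL
  anyConverged <- FALSE
  for (ini in inits) {
    o <- tryCatch(
      stats::optim(log(ini), nll, method = "L-BFGS-B",
                   lower = c(rep(log(1e-8), ne), rep(log(0.01), 5)),
                   upper = c(rep(log(50), ne), rep(log(100), 5)),
                   control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0) anyConverged <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    return(list(blens = NULL, converged = FALSE, lnL = NA_real_))
  list(blens = stats::setNames(exp(best$par[seq_len(ne)]), .edgeLabels(phy)),
       converged = anyConverged, lnL = -best$value,
       rates = c(exp(best$par[ne + 1:5]), 1))
}

#' Third-position substitution-saturation test
#'
#' Extracts the third codon positions of a gene's alignment, estimates the
#' branch lengths of the fixed species-tree topology under the general
#' time reversible (GTR) model by maximum likelihood, and flags the gene
#' as saturated when any estimated branch length reaches \code{threshold}
#' (default 1 substitution per site). Genes whose optimization fails on
#' every start are conservatively flagged saturated. Alignments with no
#' variable third positions get zero branch lengths (not saturated).
#'
#' @param alignment a \linkS4class{CodonAlignment} (>= 4 taxa).
#' @param tree tree topology (a \linkS4class{SpeciesTree} or \code{phylo}).
#' @param threshold saturation branch-length threshold.
#' @return list with \code{geneId}, \code{branchLengths} (named per
#'   branch), \code{maxBranchLength}, \code{saturated}, \code{converged},
#'   \code{reason}.
#' @export
saturationTest <- function(alignment, tree, threshold = 1.0) {
  phy <- .phyloOf(tree)
  taxaAln <- taxa(alignment)
  if (length(taxaAln) < 4L) stop("saturation test needs >= 4 taxa")
  if (length(setdiff(phy$tip.label, taxaAln)))
    phy <- ape::keep.tip(phy, intersect(phy$tip.label, taxaAln))
  chars <- thirdPositions(alignment)
  fit <- .fitGtrBranchLengths(chars, phy)
  if (is.null(fit$blens)) {
    return(list(geneId = geneId(alignment), branchLengths = NULL,
                maxBranchLength = NA_real_, saturated = TRUE,
                converged = FALSE, reason = "optimizer_failure"))
  }
  mx <- max(fit$blens)
  list(geneId = geneId(alignment), branchLengths = fit$blens,
       maxBranchLength = mx, saturated = mx >= threshold,
       converged = fit$converged,
       reason = if (mx >= threshold) "branch_length" else "pass")
}

#' @rdname saturationTest
#' @param alignments list of \linkS4class{CodonAlignment}s.
#' @return \code{saturationScreen} returns a data.frame
#'   \code{gene_id, max_branch_length, saturated, reason}.
#' @export
saturationScreen <- function(alignments, tree, threshold = 1.0) {
  rows <- lapply(alignments, function(a) {
    v <- saturationTest(a, tree, threshold)
    data.frame(gene_id = v$geneId, max_branch_length = v$maxBranchLength,
               saturated = v$saturated, reason = v$reason,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0),
                      max_branch_length = numeric(0),
                      saturated = logical(0), reason = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
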