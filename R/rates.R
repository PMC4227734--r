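#' Concatenate codon alignments gene by gene
#'
#' All alignments must share the same taxon set; columns are appended in
#' the given gene order.
#'
#' @param alignments list of \linkS4class{CodonAlignment}s.
#' @param geneId id for the concatenated alignment.
#' @return a \linkS4class{CodonAlignment}.
#' @export
concatenateAlignments <- function(alignments, geneId = "concatenated") {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  taxa0 <- sort(taxa(alignments[[1]]))
  parts <- lapply(alignments, function(a) {
    if (!identical(sort(taxa(a)), taxa0))
      stop(sprintf("gene '%s' has a different taxon set", geneId(a)))
    as.character(a@aln)[taxa0]
  })
  seqs <- do.call(paste0, parts)
  names(seqs) <- taxa0
  CodonAlignment(Biostrings::DNAStringSet(seqs), geneId = geneId)
}

#' Lineage mean rates from the concatenated super-alignment
#'
#' Concatenates all orthologs and runs one free-ratio fit on the
#' concatenation; the reported lineage "mean" Ka, Ks and Ka/Ks are the
#' concatenated fit's branch values (not averages of per-gene estimates,
#' and Ka/Ks is the fitted branch omega, not the ratio of the means).
#'
#' @param alignments list of QC-passed \linkS4class{CodonAlignment}s with
#'   a common taxon set.
#' @param tree a \linkS4class{SpeciesTree}.
#' @param lineages tip labels of the focal terminal branches.
#' @param pi codon frequency option.
#' @return data.frame with one row per lineage: \code{lineage, t, omega,
#'   Ka, Ks}; the full \linkS4class{BranchRates} in attribute
#'   \code{"fit"}.
#' @export
concatenateAndFit <- function(alignments, tree,
                              lineages = c("vlangalii", "przewalskii"),
                              pi = "f3x4") {
  concat <- concatenateAlignments(alignments)
  fit <- fitFreeRatio(concat, tree, pi = pi)
  tab <- branchRates(fit)
  rows <- lapply(lineages, function(ln) {
    r <- tab[tab$branch == ln, , drop = FALSE]
    if (nrow(r) != 1L)
      stop(sprintf("lineage '%s' is not a terminal branch of the tree", ln))
    data.frame(lineage = ln, t = r$t, omega = r$omega, Ka = r$Ka, Ks = r$Ks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holmAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Category-level binomial test for accelerated evolution
#'
#' For every functional category with more than 20 member orthologs, the
#' expected nonsynonymous substitution counts on the two focal lineages
#' are summed over member genes, rounded (half-even), and the category's
#' lineage-A share is compared with the genome-wide share
#' \code{p0 = N_A / (N_A + N_B)} by a two-sided exact binomial test, with
#' Holm correction across tested categories. The accelerated lineage is
#' the one whose share exceeds its genome-wide expectation.
#'
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{term_id}.
#' @param geneRates data.frame with columns \code{gene_id}, \code{nA},
#'   \code{nB}: per-gene expected nonsynonymous counts on lineages A
#'   and B (fractional allowed).
#' @param lineages character(2) labels reported for A and B.
#' @param minGenes minimum member count for a category to be tested
#'   (default 21, i.e. strictly more than 20 orthologs).
#' @return data.frame \code{term_id, n_genes, nA, nB, p_raw, p_holm,
#'   accelerated_lineage}; dropped small terms in attribute
#'   \code{"dropped"}.
#' @export
categoryRateTest <- function(annotations, geneRates,
                             lineages = c("A", "B"), minGenes = 21) {
  geneRates <- geneRates[!is.na(geneRates$nA) & !is.na(geneRates$nB), ]
  NA_tot <- sum(geneRates$nA)
  NB_tot <- sum(geneRates$nB)
  p0 <- NA_tot / (NA_tot + NB_tot)
  anno <- annotations[annotations$gene_id %in% geneRates$gene_id, ]
  members <- split(anno$gene_id, anno$term_id)
  sizes <- lengths(lapply(members, unique))
  dropped <- names(sizes)[sizes < minGenes]
  tested <- names(sizes)[sizes >= minGenes]
  if (length(tested) == 0L) {
    out <- data.frame(term_id = character(0), n_genes = integer(0),
                      nA = numeric(0), nB = numeric(0), p_raw = numeric(0),
                      p_holm = numeric(0),
                      accelerated_lineage = character(0))
    attr(out, "dropped") <- dropped
    return(out)
  }
  rows <- lapply(tested, function(tm) {
    g <- unique(members[[tm]])
    sel <- geneRates$gene_id %in% g
    nA <- round(sum(geneRates$nA[sel]))
    nB <- round(sum(geneRates$nB[sel]))
    if (nA + nB == 0) {
      p <- 1; acc <- NA_character_
    } else {
      p <- stats::binom.test(nA, nA + nB, p = p0,
                             alternative = "two.sided")$p.value
      share <- nA / (nA + nB)
      acc <- if (share > p0) lineages[1] else if (share < p0) lineages[2]
             else NA_character_
    }
    data.frame(term_id = tm, n_genes = length(g), nA = nA, nB = nB,
               p_raw = p, stringsAsFactors = FALSE,
               accelerated_lineage = acc)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holmAdjust(out$p_raw)
  out <- out[, c("term_id", "n_genes", "nA", "nB", "p_raw", "p_holm",
                 "accelerated_lineage")]
  attr(out, "dropped") <- dropped
  out
}

#' Per-category Ka/Ks from category concatenations
#'
#' Concatenates the member genes of each (sufficiently large) category and
#' reports the focal lineages' Ka/Ks from a free-ratio fit of the
#' concatenation -- the per-category scatter analogue of the lineage rate
#' comparison, emitted as a plain table for plotting.
#'
#' @inheritParams categoryRateTest
#' @param alignments named list of \linkS4class{CodonAlignment}s.
#' @param tree a \linkS4class{SpeciesTree}.
#' @param pi codon frequency option.
#' @return data.frame \code{term_id, n_genes, kaks_A, kaks_B}.
#' @export
categoryKaKsTable <- function(alignments, annotations, tree,
                              lineages = c("vlangalii", "przewalskii"),
                              minGenes = 21, pi = "f3x4") {
  anno <- annotations[annotations$gene_id %in% names(alignments), ]
  members <- split(anno$gene_id, anno$term_id)
  members <- members[lengths(lapply(members, unique)) >= minGenes]
  rows <- lapply(names(members), function(tm) {
    g <- unique(members[[tm]])
    summ <- concatenateAndFit(alignments[g], tree, lineages, pi = pi)
    data.frame(term_id = tm, n_genes = length(g),
               kaks_A = summ$omega[1], kaks_B = summ$omega[2],
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0), n_genes = integer(0),
                      kaks_A = numeric(0), kaks_B = numeric(0)))
  do.call(rbind, rows)
}
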