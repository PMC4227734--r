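#' Over-representation of PSGs in functional categories
#'
#' One-tailed hypergeometric over-representation tests of a gene list
#' against a background, per annotation term. The \code{"ease"} mode is the
#' conservative "modified Fisher" variant that removes one success from
#' the list before computing the tail (so \code{p_ease >= p_fisher}
#' always). Benjamini-Hochberg adjusted p-values are reported alongside
#' the raw ones.
#'
#' @param psgIds character vector of selected gene ids (subset of the
#'   background).
#' @param backgroundIds character vector of all analyzed gene ids.
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{term_id} (terms with no background member are dropped).
#' @param mode \code{"ease"} (default) or \code{"fisher"}: which p-value
#'   fills the \code{p} column used downstream.
#' @return data.frame \code{term_id, k, n, K, N, p_fisher, p_ease, p,
#'   p_adjust, genes}.
#' @export
fisherOverrepresentation <- function(psgIds, backgroundIds, annotations,
                                     mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  backgroundIds <- unique(backgroundIds)
  psgIds <- unique(psgIds)
  if (length(setdiff(psgIds, backgroundIds)))
    stop("psgIds must be a subset of backgroundIds")
  anno <- annotations[annotations$gene_id %in% backgroundIds, , drop = FALSE]
  members <- lapply(split(anno$gene_id, anno$term_id), unique)
  members <- members[lengths(members) >= 1L]
  N <- length(backgroundIds)
  n <- length(psgIds)
  rows <- lapply(names(members), function(tm) {
    g <- members[[tm]]
    K <- length(g)
    hits <- intersect(psgIds, g)
    k <- length(hits)
    pf <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pe <- if (k == 0) 1 else stats::phyper(k - 2, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(term_id = tm, k = k, n = n, K = K, N = N,
               p_fisher = pf, p_ease = pe,
               p = if (mode == "ease") pe else pf,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_fisher = numeric(0),
               p_ease = numeric(0), p = numeric(0), genes = character(0))
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Enrichment score of a category
#'
#' ES = -log10 of the geometric mean of the member term p-values; zero
#' p-values are floored at 1e-300 (with a warning). ES is symmetric in
#' its inputs and decreasing in each p; all p = 1 gives ES = 0 and two
#' p = 0.05 give ES = 1.30.
#'
#' @param p vector of p-values in (0, 1].
#' @return the enrichment score (scalar, >= 0).
#' @export
enrichmentScore <- function(p) {
  if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-values floored at 1e-300")
    p <- pmax(p, 1e-300)
  }
  -mean(log10(p))
}

#' Flag categories over-represented by PSGs
#'
#' Adds the enrichment score and the classification flag to an
#' over-representation table: a category is flagged iff ES is strictly
#' greater than \code{esThreshold} and its p-value is strictly below
#' \code{pThreshold} (an ES of exactly 1.3 is not flagged). By default
#' every term is its own cluster, so ES = -log10(p); user-supplied
#' clusters (named list of term-id groups) compute each member's ES from
#' the geometric mean over its cluster's p-values. Classification uses
#' the raw (EASE) p, with the BH-adjusted p reported alongside.
#'
#' @param results output of \code{\link{fisherOverrepresentation}}.
#' @param esThreshold ES cutoff (strict).
#' @param pThreshold p-value cutoff (strict).
#' @param clusters optional named list of character vectors of term ids.
#' @return the input data.frame with added columns \code{ES},
#'   \code{cluster} and \code{over_represented}.
#' @export
classifyOverRepresented <- function(results, esThreshold = 1.3,
                                    pThreshold = 0.05, clusters = NULL) {
  if (nrow(results) == 0L) {
    results$ES <- numeric(0)
    results$cluster <- character(0)
    results$over_represented <- logical(0)
    return(results)
  }
  if (is.null(clusters)) {
    results$ES <- -log10(pmax(results$p, 1e-300))
    results$cluster <- results$term_id
  } else {
    results$ES <- NA_real_
    results$cluster <- NA_character_
    for (cl in names(clusters)) {
      sel <- results$term_id %in% clusters[[cl]]
      if (!any(sel)) next
      results$ES[sel] <- enrichmentScore(results$p[sel])
      results$cluster[sel] <- cl
    }
    lone <- is.na(results$ES)
    results$ES[lone] <- -log10(pmax(results$p[lone], 1e-300))
    results$cluster[lone] <- results$term_id[lone]
  }
  results$over_represented <- results$ES > esThreshold &
    results$p < pThreshold
  results
}
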