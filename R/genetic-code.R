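#' @useDynLib CodonScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Internal cache for code tables built once per session.
.codonEnv <- new.env(parent = emptyenv())

.NUC <- c("A", "C", "G", "T")

#' Standard genetic code tables used throughout the package
#'
#' The package hard-codes the standard nuclear genetic code. Codons are
#' ordered lexicographically over A < C < G < T; the 61 sense codons (all
#' codons except TAA, TAG, TGA) index the state space of the codon model.
#'
#' @return \code{senseCodons()} returns the 61 sense codons in model order;
#'   \code{stopCodons()} the three stop codons; \code{codonTable()} a named
#'   character vector mapping all 64 codons to one-letter amino acids
#'   (\code{"*"} for stop).
#' @examples
#' length(senseCodons())  # 61
#' @export
senseCodons <- function() .codonTables()$sense

#' @rdname senseCodons
#' @export
stopCodons <- function() .codonTables()$stops

#' @rdname senseCodons
#' @export
codonTable <- function() .codonTables()$aa

.codonTables <- function() {
  if (!is.null(.codonEnv$tables)) return(.codonEnv$tables)
  codons <- as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
  codons <- sort(codons)  # lexicographic ACGT order
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  tabs <- list(aa = aa, stops = stops, sense = sense,
               senseIndex = stats::setNames(seq_along(sense), sense))
  .codonEnv$tables <- tabs
  tabs
}

# 61 x 61 integer matrix classifying single-nucleotide codon changes:
# 0 = not a single-step change (or identical), 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.
.codonPairTypes <- function() {
  if (!is.null(.codonEnv$pairTypes)) return(.codonEnv$pairTypes)
  tabs <- .codonTables()
  sense <- tabs$sense
  n <- length(sense)
  mat <- matrix(0L, n, n, dimnames = list(sense, sense))
  split1 <- strsplit(sense, "")
  isTransition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- which(split1[[i]] != split1[[j]])
      if (length(diffs) != 1L) next
      ts <- isTransition(split1[[i]][diffs], split1[[j]][diffs])
      syn <- tabs$aa[sense[i]] == tabs$aa[sense[j]]
      code <- if (syn && !ts) 1L else if (syn && ts) 2L else if (!syn && !ts) 3L else 4L
      mat[i, j] <- code
      mat[j, i] <- code
    }
  }
  .codonEnv$pairTypes <- mat
  mat
}

#' Codon state indices for a character vector of codons
#'
#' Maps codon strings to 1-based indices into \code{senseCodons()}; gap
#' codons (\code{"---"}), stop codons and codons containing ambiguity
#' characters map to \code{NA} (treated as missing data by the likelihood
#' engine).
#'
#' @param codons character vector of 3-letter codon strings.
#' @return integer vector of the same length.
#' @export
codonStateIndex <- function(codons) {
  idx <- .codonTables()$senseIndex[toupper(codons)]
  unname(idx)
}

#' Equal and F3x4-style codon frequency vectors
#'
#' \code{equalCodonFrequencies()} assigns 1/61 to each sense codon.
#' \code{f3x4Frequencies()} estimates position-specific nucleotide
#' frequencies from the codon columns of an alignment (gaps ignored) and
#' builds codon frequencies as their product, renormalized over the 61
#' sense codons with stop codons given zero mass.
#'
#' @param x a \linkS4class{CodonAlignment} (or a character matrix of codons)
#'   for \code{f3x4Frequencies}.
#' @param pseudocount small mass added to each nucleotide count so no sense
#'   codon gets exactly zero frequency.
#' @return named numeric vector of length 61 summing to 1.
#' @export
equalCodonFrequencies <- function() {
  sense <- senseCodons()
  stats::setNames(rep(1 / length(sense), length(sense)), sense)
}

#' @rdname equalCodonFrequencies
#' @export
f3x4Frequencies <- function(x, pseudocount = 0.5) {
  codons <- if (is.matrix(x)) x else codonMatrix(x)
  codons <- toupper(as.vector(codons))
  codons <- codons[!grepl("-", codons, fixed = TRUE)]
  if (length(codons) == 0L) return(equalCodonFrequencies())
  posFreq <- matrix(pseudocount, nrow = 3, ncol = 4,
                    dimnames = list(NULL, .NUC))
  for (p in 1:3) {
    nt <- substr(codons, p, p)
    tab <- table(factor(nt, levels = .NUC))
    posFreq[p, ] <- posFreq[p, ] + as.numeric(tab)
  }
  posFreq <- posFreq / rowSums(posFreq)
  sense <- senseCodons()
  f <- vapply(sense, function(cd) {
    posFreq[1, substr(cd, 1, 1)] * posFreq[2, substr(cd, 2, 2)] *
      posFreq[3, substr(cd, 3, 3)]
  }, numeric(1))
  f / sum(f)
}

.checkCodonFrequencies <- function(pi) {
  if (length(pi) != length(senseCodons()))
    stop("codon frequency vector must cover the 61 sense codons")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6)
    stop("codon frequencies must be non-negative and sum to 1")
  if (!is.null(names(pi)) && any(names(pi) %in% stopCodons()) &&
      any(pi[names(pi) %in% stopCodons()] > 0))
    stop("stop codons must carry zero frequency")
  pi / sum(pi)
}
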