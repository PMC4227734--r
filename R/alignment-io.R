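#' Codon matrix view of an alignment
#'
#' @param x a \linkS4class{CodonAlignment}.
#' @param validate check the object first.
#' @return character matrix, one row per taxon, one column per codon.
#' @export
codonMatrix <- function(x, validate = TRUE) {
  if (methods::is(x, "CodonAlignment")) {
    if (validate) methods::validObject(x)
    if (length(x@aln) == 0L)
      return(matrix(character(0), nrow = 0, ncol = 0))
    chars <- as.matrix(x@aln)
  } else {
    chars <- x
  }
  nc <- ncol(chars) %/% 3
  out <- matrix("", nrow = nrow(chars), ncol = nc,
                dimnames = list(rownames(chars), NULL))
  for (j in seq_len(nc)) {
    out[, j] <- paste0(chars[, 3 * j - 2], chars[, 3 * j - 1], chars[, 3 * j])
  }
  out
}

#' Third codon position characters of an alignment
#'
#' @param x a \linkS4class{CodonAlignment}.
#' @return character matrix of third-position nucleotides (taxa x sites).
#' @export
thirdPositions <- function(x) {
  chars <- as.matrix(x@aln)
  chars[, seq(3, ncol(chars), by = 3), drop = FALSE]
}

#' Read / write a codon alignment as FASTA
#'
#' FASTA headers of the form \code{species|gene_id} are split: the species
#' part becomes the taxon name and the gene id (if consistent) the
#' alignment's \code{geneId}.
#'
#' @param file path to a FASTA file.
#' @return a \linkS4class{CodonAlignment}.
#' @export
readCodonAlignment <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  nm <- names(seqs)
  gid <- sub("\\.[^.]*$", "", basename(file))
  if (all(grepl("|", nm, fixed = TRUE))) {
    parts <- strsplit(nm, "|", fixed = TRUE)
    names(seqs) <- vapply(parts, `[`, "", 1)
    gids <- unique(vapply(parts, `[`, "", 2))
    if (length(gids) == 1L) gid <- gids
  }
  CodonAlignment(seqs, geneId = gid)
}

#' @rdname readCodonAlignment
#' @param x a \linkS4class{CodonAlignment}.
#' @param withGeneId write headers as \code{species|gene_id}.
#' @export
writeCodonAlignment <- function(x, file, withGeneId = TRUE) {
  seqs <- x@aln
  if (withGeneId) names(seqs) <- paste0(names(seqs), "|", x@geneId)
  Biostrings::writeXStringSet(seqs, filepath = file)
  invisible(file)
}

# Compress an alignment into unique site patterns over the 61 codon
# states (0 = missing) for the taxa in 'taxaOrder'.
.alignmentPatterns <- function(x, taxaOrder) {
  m <- codonMatrix(x, validate = FALSE)
  miss <- setdiff(taxaOrder, rownames(m))
  if (length(miss))
    stop(sprintf("alignment '%s' lacks taxa: %s", x@geneId,
                 paste(miss, collapse = ", ")))
  m <- m[taxaOrder, , drop = FALSE]
  idx <- matrix(codonStateIndex(m), nrow = nrow(m))
  idx[is.na(idx)] <- 0L
  .compressPatterns(idx)
}

.nucPatterns <- function(chars, taxaOrder) {
  chars <- toupper(chars[taxaOrder, , drop = FALSE])
  idx <- match(chars, .NUC)
  idx <- matrix(ifelse(is.na(idx), 0L, idx), nrow = nrow(chars))
  .compressPatterns(idx)
}

# as.character() drops names from plain character vectors; keep them.
.namedChars <- function(x) {
  v <- as.character(x)
  if (is.null(names(v))) names(v) <- names(x)
  v
}

.compressPatterns <- function(idx) {
  if (ncol(idx) == 0L)
    return(list(states = idx, weights = numeric(0)))
  key <- apply(idx, 2, paste, collapse = ",")
  f <- factor(key, levels = unique(key))
  first <- match(levels(f), key)
  list(states = idx[, first, drop = FALSE], weights = as.numeric(tabulate(f)))
}
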