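# Reciprocal-best-hit orthology via translated local alignment: a
# six-frame x three-frame Smith-Waterman peptide search standing in for a
# translated BLAST search. Internal stop codons are effectively forbidden
# in alignments by a large negative score, and significance is a raw-score
# threshold (calibratable on shuffled-sequence nulls) rather than an
# e-value.

.defaultScoring <- function(gapOpening = 11, gapExtension = 1,
                            stopPenalty = -1000) {
  mat <- .blosum62()
  mat["*", ] <- stopPenalty
  mat[, "*"] <- stopPenalty
  mat["*", "*"] <- stopPenalty
  list(matrix = mat, gapOpening = gapOpening, gapExtension = gapExtension)
}

.blosum62 <- function() {
  if (!is.null(.codonEnv$blosum62)) return(.codonEnv$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  .codonEnv$blosum62 <- env$BLOSUM62
  env$BLOSUM62
}

.revComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "")[[1]]),
        collapse = "")
}

# Translate one reading frame; frame in {1,2,3,-1,-2,-3}; returns a plain
# character string (X for ambiguous codons, * for stops).
.translateFrame <- function(seq, frame) {
  s <- toupper(as.character(seq))
  if (frame < 0) s <- .revComp(s)
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  n <- n - n %% 3L
  if (n < 3L) return("")
  starts <- off + seq(1L, n, 3L)
  aa <- codonTable()[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Best translated local-alignment hit between two nucleotide sequences
#'
#' Scores every pairing of the six reading frames of \code{query} with the
#' three forward frames of \code{target} by Smith-Waterman on the
#' translated peptides (BLOSUM62, affine gaps, stop codons effectively
#' forbidden) and returns the maximum-scoring hit. Scores are floored at 0
#' (an all-ambiguous sequence scores 0). Coordinates are 0-based,
#' half-open, in nucleotides on the input strings; the sign of the query
#' frame encodes the strand.
#'
#' @param query,target nucleotide sequences (character or DNAString).
#' @param scoring list with \code{matrix}, \code{gapOpening},
#'   \code{gapExtension}; defaults to BLOSUM62 with gap open 11 / extend 1.
#' @return list with \code{query}, \code{target}, \code{score},
#'   \code{queryFrame}, \code{targetFrame}, \code{queryRange},
#'   \code{targetRange} (0-based half-open nucleotide spans).
#' @export
translatedSimilarity <- function(query, target, scoring = .defaultScoring()) {
  query <- as.character(query); target <- as.character(target)
  if (nchar(query) < 3L || nchar(target) < 3L)
    stop("sequences must contain at least one codon")
  alphabet <- rownames(scoring$matrix)
  best <- list(score = -Inf)
  for (qf in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    qa <- .encodePeptide(.translateFrame(query, qf), alphabet)
    if (length(qa) == 0L) next
    for (tf in 1:3) {
      tb <- .encodePeptide(.translateFrame(target, tf), alphabet)
      if (length(tb) == 0L) next
      hit <- cpp_sw_ends(qa, tb, scoring$matrix, scoring$gapOpening,
                         scoring$gapExtension)
      if (hit[1] > best$score && hit[1] > 0) {
        # rerun on the reversed prefixes to locate the alignment start
        rev2 <- cpp_sw_ends(rev(qa[seq_len(hit[2])]),
                            rev(tb[seq_len(hit[3])]), scoring$matrix,
                            scoring$gapOpening, scoring$gapExtension)
        best <- list(score = hit[1], qf = qf, tf = tf,
                     qaa = c(hit[2] - rev2[2] + 1, hit[2]),
                     taa = c(hit[3] - rev2[3] + 1, hit[3]))
      }
    }
  }
  if (!is.finite(best$score))
    return(list(query = query, target = target, score = 0,
                queryFrame = 1L, targetFrame = 1L,
                queryRange = c(0L, 0L), targetRange = c(0L, 0L)))
  qr <- .aaSpanToNt(best$qaa, best$qf, nchar(query))
  tr <- .aaSpanToNt(best$taa, best$tf, nchar(target))
  list(query = query, target = target, score = max(0, best$score),
       queryFrame = best$qf, targetFrame = best$tf,
       queryRange = qr, targetRange = tr)
}

# Convert a 1-based peptide span in a given frame to a 0-based half-open
# nucleotide span on the original (forward) sequence.
.aaSpanToNt <- function(aaSpan, frame, seqLen) {
  off <- abs(frame) - 1L
  s <- off + 3L * (aaSpan[1] - 1L)        # 0-based on translated strand
  e <- off + 3L * aaSpan[2]               # half-open
  if (frame > 0) c(s, e) else c(seqLen - e, seqLen - s)
}

# 0-based integer encoding of a peptide in the scoring matrix's alphabet.
.encodePeptide <- function(pep, alphabet) {
  idx <- match(strsplit(as.character(pep), "")[[1]], alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  as.integer(idx - 1L)
}

.encodeFrames <- function(seqs, alphabet, frames = c(1L, 2L, 3L, -1L, -2L, -3L)) {
  lapply(seqs, function(s)
    lapply(frames, function(f) .encodePeptide(.translateFrame(s, f),
                                              alphabet)))
}

# Pairwise score matrix between two sequence sets: max over the 6 query
# frames x 3 target frames of the local-alignment peptide score.
.similarityScoreMatrix <- function(setA, setB, scoring = .defaultScoring()) {
  a <- .namedChars(setA); b <- .namedChars(setB)
  alphabet <- rownames(scoring$matrix)
  encA <- .encodeFrames(a, alphabet)
  encB <- .encodeFrames(b, alphabet, frames = 1:3)
  S <- matrix(0, length(a), length(b),
              dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      best <- 0
      for (qa in encA[[i]]) {
        if (length(qa) == 0L) next
        for (tb in encB[[j]]) {
          if (length(tb) == 0L) next
          sc <- cpp_sw_score(qa, tb, scoring$matrix,
                             scoring$gapOpening, scoring$gapExtension)
          if (sc > best) best <- sc
        }
      }
      S[i, j] <- best
    }
  }
  S
}

#' Identify 1:1 orthologs by best reciprocal hit
#'
#' A transcript/CDS pair is reported iff each is the unique top-scoring
#' hit of the other, both scores reach \code{minScore}, and the aligned
#' region covers at least \code{minHitFraction} of the shorter translated
#' length. Ties for a best hit drop the sequence from pairing (logged in
#' the \code{"dropped"} attribute), keeping only unambiguous 1:1 pairs.
#'
#' @param transcripts,referenceCds named \code{DNAStringSet}s (or
#'   character vectors).
#' @param minScore raw-score significance threshold; see
#'   \code{\link{calibrateScoreThreshold}}.
#' @param minHitFraction minimum aligned fraction of the shorter
#'   translated sequence.
#' @param scoring scoring scheme as in \code{\link{translatedSimilarity}}.
#' @return data.frame \code{transcript_id, cds_id, fwd_score, rev_score}
#'   (scores are equal under this symmetric scorer); dropped ties in
#'   attribute \code{"dropped"}.
#' @export
bestReciprocalHits <- function(transcripts, referenceCds, minScore = 60,
                               minHitFraction = 0.3,
                               scoring = .defaultScoring()) {
  if (length(transcripts) == 0L || length(referenceCds) == 0L)
    stop("both sequence sets must be non-empty")
  tr <- .namedChars(transcripts)
  cd <- .namedChars(referenceCds)
  if (is.null(names(tr))) names(tr) <- sprintf("tr_%d", seq_along(tr))
  if (is.null(names(cd))) names(cd) <- sprintf("cds_%d", seq_along(cd))
  S <- .similarityScoreMatrix(tr, cd, scoring)
  dropped <- character(0)
  pairs <- list()
  for (i in seq_len(nrow(S))) {
    sc <- S[i, ]
    top <- max(sc)
    if (top < minScore) next
    j <- which(sc == top)
    if (length(j) > 1L) { dropped <- c(dropped, names(tr)[i]); next }
    back <- S[, j]
    if (sum(back == max(back)) > 1L) { dropped <- c(dropped, names(tr)[i]); next }
    if (which.max(back) != i) next
    if (max(back) < minScore) next
    hit <- translatedSimilarity(tr[[i]], cd[[j]], scoring)
    alnLen <- (hit$queryRange[2] - hit$queryRange[1]) / 3
    shorter <- min(nchar(tr[[i]]), nchar(cd[[j]])) / 3
    if (alnLen < minHitFraction * shorter) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      transcript_id = names(tr)[i], cds_id = names(cd)[j],
      fwd_score = top, rev_score = max(back), stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(transcript_id = character(0), cds_id = character(0),
               fwd_score = numeric(0), rev_score = numeric(0))
  attr(out, "dropped") <- dropped
  out
}

#' Calibrate the raw-score significance threshold on shuffled nulls
#'
#' Scores pairs of independently shuffled sequences drawn from the input
#' sets and returns an upper quantile of the null score distribution, the
#' package's stand-in for a translated-BLAST e-value cutoff.
#'
#' @param sequences pool of sequences to shuffle (character or
#'   DNAStringSet).
#' @param nShuffles number of shuffled pairs.
#' @param probs quantile of the null distribution to return.
#' @param seed RNG seed.
#' @param scoring scoring scheme.
#' @return the score threshold (scalar).
#' @export
calibrateScoreThreshold <- function(sequences, nShuffles = 10000,
                                    probs = 0.99999, seed = 1,
                                    scoring = .defaultScoring()) {
  set.seed(seed)
  seqs <- as.character(sequences)
  shuffleOne <- function() {
    s <- seqs[[sample.int(length(seqs), 1)]]
    paste0(sample(strsplit(s, "")[[1]]), collapse = "")
  }
  alphabet <- rownames(scoring$matrix)
  scores <- vapply(seq_len(nShuffles), function(i) {
    qa <- .encodeFrames(shuffleOne(), alphabet)[[1]]
    tb <- .encodeFrames(shuffleOne(), alphabet, frames = 1:3)[[1]]
    best <- 0
    for (q in qa) {
      if (length(q) == 0L) next
      for (t in tb) {
        if (length(t) == 0L) next
        sc <- cpp_sw_score(q, t, scoring$matrix, scoring$gapOpening,
                           scoring$gapExtension)
        if (sc > best) best <- sc
      }
    }
    best
  }, numeric(1))
  unname(stats::quantile(scores, probs = probs, type = 1))
}
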