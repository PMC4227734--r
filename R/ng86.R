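# Nei-Gojobori (1986)-style pairwise Ka/Ks by site counting with
# Jukes-Cantor correction. This is deliberately independent of the
# likelihood machinery and serves as its counting cross-check.

# Synonymous site count of one codon: per position, the fraction of the
# three possible single-nucleotide changes that are synonymous; changes
# creating stop codons count as nonsynonymous.
.synSitesPerCodon <- function() {
  if (!is.null(.codonEnv$synSites)) return(.codonEnv$synSites)
  aa <- codonTable()
  sense <- senseCodons()
  out <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (p in 1:3) {
      for (nt in setdiff(.NUC, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- nt
        if (aa[alt] != "*" && aa[alt] == aa[cd]) s <- s + 1 / 3
      }
    }
    out[cd] <- s
  }
  .codonEnv$synSites <- out
  out
}

# Average synonymous/nonsynonymous difference counts between two codons
# over all mutational pathways (orderings of the differing positions).
# Steps through or to stop codons count as nonsynonymous.
.codonDiffCounts <- function(a, b) {
  aa <- codonTable()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1L) list(pos) else
    lapply(.permutations(nd), function(o) pos[o])
  tot <- c(syn = 0, nonsyn = 0)
  for (path in paths) {
    cur <- a
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      syn <- aa[cur] != "*" && aa[nxt] != "*" && aa[cur] == aa[nxt]
      tot <- tot + if (syn) c(1, 0) else c(0, 1)
      cur <- nxt
    }
  }
  tot / length(paths)
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Pairwise Ka and Ks by NG86-style counting
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over mutational pathways for
#' codons differing at more than one position), converts proportions to
#' distances with the Jukes-Cantor correction, and returns Ka, Ks and
#' their ratio. Codons containing gaps, ambiguity characters or stops are
#' skipped in both sequences. Proportions of 0.75 or more are beyond the
#' correction's reach and yield \code{NA} (saturation marker). The
#' statistic is symmetric in its arguments.
#'
#' @param seqA,seqB equal-length in-frame nucleotide sequences.
#' @return list with \code{Ka}, \code{Ks}, \code{omega} (\code{Ka/Ks};
#'   \code{NA} when \code{Ks} is 0 or undefined), and the underlying
#'   counts \code{S}, \code{N}, \code{sd}, \code{nd}.
#' @export
ng86Pairwise <- function(seqA, seqB) {
  seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
  if (nchar(seqA) != nchar(seqB)) stop("sequences must have equal length")
  if (nchar(seqA) %% 3 != 0) stop("sequence length must be a multiple of 3")
  n <- nchar(seqA) %/% 3
  codA <- substring(seqA, 3 * seq_len(n) - 2, 3 * seq_len(n))
  codB <- substring(seqB, 3 * seq_len(n) - 2, 3 * seq_len(n))
  sense <- senseCodons()
  usable <- codA %in% sense & codB %in% sense
  codA <- codA[usable]; codB <- codB[usable]
  if (length(codA) == 0L)
    return(list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
                S = 0, N = 0, sd = 0, nd = 0))
  synSites <- .synSitesPerCodon()
  S <- sum((synSites[codA] + synSites[codB]) / 2)
  N <- 3 * length(codA) - S
  sd <- 0; nd <- 0
  for (i in which(codA != codB)) {
    d <- .codonDiffCounts(codA[i], codB[i])
    sd <- sd + d["syn"]; nd <- nd + d["nonsyn"]
  }
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- if (S > 0) jc(sd / S) else NA_real_
  Ka <- if (N > 0) jc(nd / N) else NA_real_
  omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  list(Ka = unname(Ka), Ks = unname(Ks), omega = unname(omega),
       S = unname(S), N = unname(N), sd = unname(sd), nd = unname(nd))
}
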