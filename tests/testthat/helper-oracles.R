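# Independent oracles and small fixtures shared by the tests. Everything
# here is deliberately written from first principles (enumeration, brute
# force, closed forms) and kept separate from the package's own code
# paths.

.tinyTree4 <- function(b = c(0.1, 0.2, 0.15, 0.3, 0.25)) {
  # unrooted 4-taxon tree ((A,B),C,D) with 5 branches
  txt <- sprintf("((A:%f,B:%f):%f,C:%f,D:%f);", b[1], b[2], b[3], b[4], b[5])
  readSpeciesTree(txt)
}

# Brute-force codon-tree likelihood for the unrooted 4-taxon tree
# ((A,B),C,D): sum over both internal node states. P matrices are built
# with Matrix::expm from the package's (separately tested) rate matrix,
# so the exponential route is independent of the eigendecomposition
# used by the engine.
bruteForceLogLik4 <- function(codonRows, b, kappa, omega, pi) {
  Q <- codonRateMatrix(kappa, omega, pi)
  P <- lapply(b, function(t) as.matrix(Matrix::expm(Q * t)))
  sense <- senseCodons()
  idx <- apply(codonRows, 2, function(col) match(col, sense))
  ns <- length(sense)
  total <- 0
  for (s in seq_len(ncol(codonRows))) {
    st <- idx[, s]
    lik <- 0
    for (u in seq_len(ns)) {      # internal node joining A, B
      pAB <- .tipP(P[[1]], u, st[1]) * .tipP(P[[2]], u, st[2])
      if (pAB == 0) next
      for (v in seq_len(ns)) {    # internal node joining C, D (root)
        lik <- lik + pi[v] * P[[3]][v, u] * pAB *
          .tipP(P[[4]], v, st[3]) * .tipP(P[[5]], v, st[4])
      }
    }
    total <- total + log(lik)
  }
  total
}

.tipP <- function(P, from, to) {
  if (is.na(to)) 1 else P[from, to]  # NA = missing data, marginalized
}

# Quadratic-space affine-gap local alignment DP oracle on peptides.
swOracle <- function(a, b, mat, gapOpen, gapExt) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (vertical)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, E[i - 1, j] - gapExt)
      F[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, F[i, j - 1] - gapExt)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exact two-sided binomial p-value by full enumeration (sum of all
# outcome probabilities not exceeding that of the observed outcome).
binomTwoSidedOracle <- function(x, n, p) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Hypergeometric upper tail by enumeration: P(X >= k) drawing n from a
# population of N with K successes.
hyperTailOracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Step-down Holm by its definition.
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random in-frame CDS of n codons (no stops by construction).
randomCds <- function(n) {
  paste0(senseCodons()[sample.int(61, n, replace = TRUE)], collapse = "")
}

# Simulate 4-state nucleotide columns on a tree under GTR with unit-flux
# scaling, independent of the package engine (direct matrix exponential).
simThirdPositions <- function(phy, nSites, rates = rep(1, 6),
                              freqs = rep(0.25, 4)) {
  M <- matrix(0, 4, 4)
  M[lower.tri(M)] <- rates
  M <- M + t(M)
  Q <- M %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(freqs * -diag(Q))
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  states <- matrix(0L, nnode, nSites)
  root <- ntip + 1L
  states[root, ] <- sample.int(4, nSites, replace = TRUE, prob = freqs)
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
  E <- phy$edge
  for (k in seq_len(nrow(E))) {
    P <- as.matrix(Matrix::expm(Q * phy$edge.length[k]))
    par <- E[k, 1]; ch <- E[k, 2]
    for (st in 1:4) {
      i <- which(states[par, ] == st)
      if (length(i))
        states[ch, i] <- sample.int(4, length(i), replace = TRUE,
                                    prob = P[st, ])
    }
  }
  nuc <- c("A", "C", "G", "T")
  out <- matrix(nuc[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(out) <- phy$tip.label
  out
}

# Wrap third-position columns into a codon alignment whose first two
# positions are a fixed non-degenerate prefix ("GC" = alanine, so any
# third base is sense).
codonsFromThirds <- function(thirds, geneId = "g") {
  seqs <- apply(thirds, 1, function(row) paste0("GC", row, collapse = ""))
  CodonAlignment(Biostrings::DNAStringSet(seqs), geneId = geneId)
}
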