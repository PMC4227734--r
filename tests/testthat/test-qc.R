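test_that("consensus calls follow the most-reads rule with documented ties", {
  expect_equal(consensusCall(c(A = 10, C = 0, G = 3, T = 0)), "A")
  expect_equal(consensusCall(c(A = 0, C = 0, G = 0, T = 0)), "N")
  # alphabetical tie rule, verified by enumeration of all tie patterns
  nuc <- c("A", "C", "G", "T")
  for (k in 2:4) {
    combs <- combn(4, k)
    for (j in seq_len(ncol(combs))) {
      counts <- stats::setNames(rep(0, 4), nuc)
      counts[combs[, j]] <- 5
      expect_equal(consensusCall(counts), nuc[combs[1, j]])
    }
  }
  # matrix input, one call per row
  m <- rbind(c(A = 2, C = 9, G = 0, T = 0), c(A = 1, C = 1, G = 1, T = 1))
  expect_equal(consensusCall(m), c("C", "A"))
  expect_error(consensusCall(c(A = -1, C = 0, G = 0, T = 0)))
})

test_that("block trimming keeps conserved runs and drops gappy columns", {
  # fully conserved, gap-free: unchanged
  row <- strrep("ATGGCC", 20)
  aln <- CodonAlignment(c(a = row, b = row, c = row, d = row), geneId = "t1")
  expect_identical(as.character(trimAlignmentBlocks(aln)@aln),
                   as.character(aln@aln))
  # 30 conserved + 4 gap-riddled + 30 conserved -> 60 codons
  good <- strrep("ATG", 30)
  gappy <- strrep("---", 4)
  seqs <- c(a = paste0(good, gappy, good),
            b = paste0(good, strrep("ATG", 4), good),
            c = paste0(good, gappy, good),
            d = paste0(good, strrep("ATG", 4), good))
  tr <- trimAlignmentBlocks(CodonAlignment(seqs, geneId = "t2"),
                            minBlock = 5, maxGapFraction = 0)
  expect_equal(numCodons(tr), 60)
  # with maxGapFraction = 0 any gap kills the column even if short runs remain
  expect_false(any(grepl("-", as.character(tr@aln), fixed = TRUE)))
  # trimming is idempotent
  tr2 <- trimAlignmentBlocks(tr, minBlock = 5, maxGapFraction = 0)
  expect_identical(as.character(tr2@aln), as.character(tr@aln))
})

test_that("length/stop filter keeps the 200 bp boundary exactly", {
  mk <- function(n, id) {
    s <- randomCds(n)
    CodonAlignment(c(a = s, b = s, c = s, d = s, e = s), geneId = id)
  }
  set.seed(31)
  a66 <- mk(66, "g66")    # 198 bp
  a67 <- mk(67, "g67")    # 201 bp
  a300 <- mk(300, "g300")
  stopSeq <- paste0(randomCds(40), "TAA", randomCds(40))
  aStop <- CodonAlignment(c(a = stopSeq, b = randomCds(81), c = randomCds(81),
                            d = randomCds(81)), geneId = "gstop")
  res <- filterOrthologs(list(a66, a67, a300, aStop))
  expect_setequal(names(res$kept), c("g67", "g300"))
  expect_equal(res$log$reason[res$log$gene_id == "g66"], "too_short")
  expect_equal(res$log$reason[res$log$gene_id == "gstop"], "stop_codon")
  # filtering the kept set again changes nothing
  res2 <- filterOrthologs(res$kept)
  expect_identical(names(res2$kept), names(res$kept))
})

test_that("GTR engine agrees with brute force and an independent fitter", {
  ns <- asNamespace("CodonScan")
  # brute-force check of the GTR likelihood on 4 taxa x 3 sites
  phy <- .tinyTree4(c(0.2, 0.1, 0.15, 0.3, 0.25))@tree
  chars <- rbind(A = c("A", "C", "G"), B = c("A", "T", "G"),
                 C = c("C", "C", "G"), D = c("A", "C", "T"))
  freqs <- c(0.3, 0.2, 0.25, 0.25)
  rates <- c(1.2, 2.5, 0.8, 1.1, 3, 1)
  eng <- ns$.treeEngine(phy)
  eig <- ns$.gtrEigen(rates, freqs)
  Pc <- ns$.buildPcube(eig, eng$len)
  pat <- ns$.nucPatterns(chars, phy$tip.label)
  lnl <- sum(pat$weights *
               log(as.vector(ns$cpp_sitelik(pat$states, eng$edge, Pc,
                                            eng$nnodes, eng$root, freqs))))
  # enumeration over both internal nodes
  M <- matrix(0, 4, 4); M[lower.tri(M)] <- rates; M <- M + t(M)
  Q <- M %*% diag(freqs); diag(Q) <- -rowSums(Q)
  Q <- Q / sum(freqs * -diag(Q))
  # P indexed as (A-tip, B-tip, internal, C-tip, D-tip) branches
  P <- lapply(c(0.2, 0.1, 0.15, 0.3, 0.25),
              function(t) as.matrix(Matrix::expm(Q * t)))
  nuc <- c("A", "C", "G", "T")
  oracle <- 0
  for (s in 1:3) {
    idx <- match(chars[, s], nuc)
    lik <- 0
    for (u in 1:4) for (v in 1:4) {
      lik <- lik + freqs[v] * P[[3]][v, u] * P[[1]][u, idx[1]] *
        P[[2]][u, idx[2]] * P[[4]][v, idx[3]] * P[[5]][v, idx[4]]
    }
    oracle <- oracle + log(lik)
  }
  expect_lt(abs(lnl - oracle) / abs(oracle), 1e-10)
  # branch-length recovery cross-checked against phangorn on one dataset
  skip_if_not_installed("phangorn")
  set.seed(32)
  st5 <- defaultSpeciesTree()@tree
  thirds <- simThirdPositions(st5, 1500)
  fit <- ns$.fitGtrBranchLengths(thirds, st5)
  dat <- phangorn::phyDat(thirds)
  pml0 <- phangorn::pml(ape::unroot(st5), dat)
  pml1 <- phangorn::optim.pml(pml0, optEdge = TRUE, optBf = TRUE,
                              optQ = TRUE,
                              control = phangorn::pml.control(trace = 0))
  expect_equal(sum(fit$blens), sum(pml1$tree$edge.length), tolerance = 0.1)
})

test_that("saturation screen flags long branches and spares clean genes", {
  ns <- asNamespace("CodonScan")
  st <- defaultSpeciesTree()
  # identical sequences: all branch lengths ~0, never saturated
  s <- strrep("GCA", 120)
  same <- CodonAlignment(c(vlangalii = s, przewalskii = s, anolis = s,
                           gallus = s, pelodiscus = s), geneId = "same")
  v <- saturationTest(same, st)
  expect_false(v$saturated)
  expect_equal(v$maxBranchLength, 0)
  # mutually independent random third positions: long branches everywhere
  set.seed(33)
  thirds <- matrix(sample(c("A", "C", "G", "T"), 5 * 400, replace = TRUE),
                   nrow = 5)
  rownames(thirds) <- st@tree$tip.label
  rand <- codonsFromThirds(thirds)
  vr <- saturationTest(rand, st)
  expect_true(vr$saturated)
})

test_that("third-position branch lengths are recovered from simulations", {
  set.seed(34)
  phy <- defaultSpeciesTree()@tree
  ns <- asNamespace("CodonScan")
  for (tTrue in c(0.05, 0.2, 0.5)) {
    phy2 <- phy
    phy2$edge.length <- rep(tTrue, 7)
    thirds <- simThirdPositions(phy2, 2000)
    fit <- ns$.fitGtrBranchLengths(thirds, phy2)
    # typical (median) per-branch recovery; single branches fluctuate
    # with the sampling noise of 2,000 sites
    expect_lt(median(abs(fit$blens - tTrue) / tTrue), 0.15)
    expect_lt(abs(sum(fit$blens) - 7 * tTrue) / (7 * tTrue), 0.15)
  }
})
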