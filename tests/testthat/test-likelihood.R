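test_that("two-taxon likelihood matches the closed form", {
  pi <- equalCodonFrequencies()
  tt <- readSpeciesTree("(A:0.2,B:0.3);")
  aln <- CodonAlignment(c(A = "ATGAAA", B = "ATGAAG"), geneId = "pair")
  lnl <- codonLogLik(aln, tt, kappa = 2, omega = 0.5, pi = pi)
  Q <- codonRateMatrix(2, 0.5, pi)
  P <- as.matrix(Matrix::expm(Q * 0.5))   # reversible: only total length
  sense <- senseCodons()
  direct <- log(pi["ATG"] * P["ATG", "ATG"]) +
    log(pi["AAA"] * P["AAA", "AAG"])
  expect_equal(lnl, unname(direct), tolerance = 1e-9)
})

test_that("pruning equals brute-force enumeration, including missing data", {
  set.seed(42)
  pi <- equalCodonFrequencies()
  b <- c(0.12, 0.3, 0.08, 0.4, 0.22)
  st <- .tinyTree4(b)
  sense <- senseCodons()
  codons <- matrix(sense[sample.int(61, 12, replace = TRUE)], nrow = 4)
  codons[2, 3] <- "---"   # gap codon -> marginalized
  rownames(codons) <- c("A", "B", "C", "D")
  aln <- CodonAlignment(codons, geneId = "bf")
  for (pars in list(c(2, 0.3), c(3.1, 1.7))) {
    lnl <- codonLogLik(aln, st, kappa = pars[1], omega = pars[2], pi = pi)
    oracle <- bruteForceLogLik4(codons, b, pars[1], pars[2], pi)
    expect_lt(abs(lnl - oracle) / abs(oracle), 1e-10)
  }
})

test_that("likelihood is invariant to the rooting of the unrooted tree", {
  set.seed(7)
  pi <- equalCodonFrequencies()
  st <- defaultSpeciesTree()
  a <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, omega = 0.4),
                              30, seed = 7)
  base <- codonLogLik(a, st, kappa = 2, omega = 0.4, pi = pi)
  phy <- ape::unroot(st@tree)
  for (og in c("gallus", "anolis", "vlangalii")) {
    rerooted <- ape::root(phy, outgroup = og, resolve.root = FALSE)
    lnl <- codonLogLik(a, SpeciesTree(rerooted), kappa = 2, omega = 0.4,
                       pi = pi)
    expect_lt(abs(lnl - base), 1e-9)
  }
})

test_that("mixture likelihood interpolates its component classes", {
  pi <- equalCodonFrequencies()
  st <- defaultSpeciesTree()
  a <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, omega = 0.4),
                              40, seed = 8)
  cls <- data.frame(proportion = c(0.5, 0.5), background = c(0.2, 0.2),
                    foreground = c(0.2, 0.2))
  expect_equal(codonLogLik(a, st, kappa = 2, classes = cls, pi = pi),
               codonLogLik(a, st, kappa = 2, omega = 0.2, pi = pi),
               tolerance = 1e-9)
  expect_error(codonLogLik(a, st, kappa = 2,
                           classes = data.frame(proportion = c(0.6, 0.6),
                                                background = c(0.1, 1),
                                                foreground = c(0.1, 1))),
               "sum to 1")
  bad <- CodonAlignment(c(X = "ATG"), geneId = "bad")
  expect_error(codonLogLik(bad, st, kappa = 2, omega = 0.3),
               "not in tree")
})
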