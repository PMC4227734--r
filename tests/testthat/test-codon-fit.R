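test_that("one-ratio fit recovers its generating parameters", {
  st <- defaultSpeciesTree()
  pi <- equalCodonFrequencies()
  a <- simulateCodonAlignment(st, list(kappa = 2.5, pi = pi, omega = 0.2),
                              800, seed = 41)
  ns <- asNamespace("CodonScan")
  m0 <- ns$.fitM0(ns$.fitContext(a, st, "equal"))
  expect_equal(m0$omega, 0.2, tolerance = 0.05)
  expect_equal(m0$kappa, 2.5, tolerance = 0.5)
  expect_equal(unname(m0$blens), st@tree$edge.length, tolerance = 0.35)
})

test_that("branch-site test degenerates correctly on identical sequences", {
  st <- defaultSpeciesTree()
  s <- randomCds(80)
  same <- CodonAlignment(stats::setNames(rep(s, 5), st@tree$tip.label),
                         geneId = "flat")
  fit <- fitBranchSite(same, st, pi = "equal")
  expect_equal(fit@lrt, 0, tolerance = 1e-6)
  expect_equal(fit@pValue, 1, tolerance = 1e-6)
  expect_false(isPSG(fit))
})

test_that("alternative never falls below the null and invariants hold", {
  st <- defaultSpeciesTree()
  pi <- equalCodonFrequencies()
  ns <- asNamespace("CodonScan")
  set.seed(42)
  for (i in 1:3) {
    cls <- ns$.branchSiteClasses(0.45, 0.45, 0.1, sample(c(1, 3), 1))
    a <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, classes = cls),
                                120)
    fit <- fitBranchSite(a, st, pi = "equal")
    expect_gte(fit@lnLAlt, fit@lnLNull - 1e-6)
    expect_gte(fit@lrt, 0)
    expect_true(fit@pValue >= 0 && fit@pValue <= 1)
    expect_lte(fit@p0 + fit@p1, 1 + 1e-8)
    expect_gte(fit@omega2, 1)
    expect_true(fit@omega0 < 1)
  }
})

test_that("deterministic multi-start lands on one optimum", {
  # genes drawn under the study conditions (mixed lengths, 20% selected);
  # very short null genes have flat surfaces where shallow secondary
  # optima are a known feature of the model
  st <- defaultSpeciesTree()
  pi <- equalCodonFrequencies()
  ns <- asNamespace("CodonScan")
  set.seed(90)
  agree <- vapply(1:8, function(i) {
    w2 <- if (i <= 2) 5 else 1
    len <- sample(150:450, 1)
    cls <- ns$.branchSiteClasses(0.4, 0.4, 0.15, w2)
    a <- simulateCodonAlignment(st, list(kappa = 2.5, pi = pi,
                                         classes = cls), len)
    fit <- fitBranchSite(a, st, pi = "equal", fullStarts = TRUE)
    diff(range(fit@diagnostics$startLnLs)) < 1e-4
  }, logical(1))
  expect_gte(sum(agree), 7)   # 95%-style agreement on a small panel
})

test_that("free-ratio fit is internally consistent and degenerates cleanly", {
  st <- defaultSpeciesTree()
  s <- randomCds(90)
  same <- CodonAlignment(stats::setNames(rep(s, 5), st@tree$tip.label),
                         geneId = "flat")
  fr <- fitFreeRatio(same, st, pi = "equal")
  tab <- branchRates(fr)
  expect_true(all(tab$t < 1e-4))
  expect_true(all(tab$Ka == 0 & tab$Ks == 0))
  expect_true(all(is.na(tab$omega)))
  # Ka/Ks equals omega wherever defined
  pi <- equalCodonFrequencies()
  a <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, omega = 0.3),
                              300, seed = 44)
  fr2 <- fitFreeRatio(a, st, pi = "equal")
  tab2 <- branchRates(fr2)
  ok <- !is.na(tab2$omega) & tab2$Ks > 0
  expect_true(any(ok))
  expect_equal(tab2$Ka[ok] / tab2$Ks[ok], tab2$omega[ok], tolerance = 1e-6)
})

test_that("two-taxon free-ratio recovers omega and matches NG86 counting", {
  tt <- readSpeciesTree("(A:0.25,B:0.25);")
  pi <- equalCodonFrequencies()
  a <- simulateCodonAlignment(tt, list(kappa = 2, pi = pi, omega = 0.3),
                              6000, seed = 45)
  fr <- fitFreeRatio(a, tt, pi = "equal")
  tab <- branchRates(fr)
  expect_equal(tab$omega, 0.3, tolerance = 0.05)
  expect_equal(tab$t, 0.5, tolerance = 0.05)
  m <- codonMatrix(a)
  ng <- ng86Pairwise(paste(m[1, ], collapse = ""),
                     paste(m[2, ], collapse = ""))
  expect_lt(abs(ng$omega - tab$omega) / tab$omega, 0.2)
})

test_that("NG86 counting handles its edge cases", {
  s <- randomCds(50)
  same <- ng86Pairwise(s, s)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  # one synonymous change (CTT -> CTC, both Leu)
  a <- paste0("CTT", randomCds(20))
  b <- paste0("CTC", substr(a, 4, nchar(a)))
  one <- ng86Pairwise(a, b)
  expect_equal(one$Ka, 0)
  expect_gt(one$Ks, 0)
  # symmetry
  set.seed(46)
  x <- randomCds(60); y <- randomCds(60)
  expect_equal(ng86Pairwise(x, y), ng86Pairwise(y, x))
  # gap codons are skipped in both sequences
  gap <- ng86Pairwise(paste0("---", substr(a, 4, nchar(a))), b)
  expect_equal(gap$S + gap$N, 3 * 20)
  expect_error(ng86Pairwise("ATG", "ATGAAA"))
})

test_that("scan tabulates fits and flags PSGs at the threshold", {
  st <- defaultSpeciesTree()
  pi <- equalCodonFrequencies()
  ns <- asNamespace("CodonScan")
  set.seed(47)
  alns <- lapply(1:3, function(i) {
    cls <- ns$.branchSiteClasses(0.4, 0.4, 0.15, if (i == 1) 8 else 1)
    simulateCodonAlignment(st, list(kappa = 2.5, pi = pi, classes = cls),
                           200, geneId = sprintf("g%d", i))
  })
  tab <- scanPositiveSelection(alns, st, alpha = 0.05, pi = "equal")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$psg_flag, tab$p_value < 0.05)
  expect_true(all(c("gene_id", "lnl_alt", "lnl_null", "lrt", "p_value",
                    "omega2", "psg_flag") %in% names(tab)))
})
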