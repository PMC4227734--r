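test_that("degenerate simulations behave as forced", {
  pi <- equalCodonFrequencies()
  st0 <- defaultSpeciesTree(branchLengths = rep(0, 7))
  a <- simulateCodonAlignment(st0, list(kappa = 2, pi = pi, omega = 0.5),
                              50, seed = 1)
  seqs <- as.character(a@aln)
  expect_true(all(seqs == seqs[[1]]))   # zero branch lengths: no change
  # omega = 0: amino-acid sequences identical across taxa
  st <- defaultSpeciesTree()
  a0 <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, omega = 0),
                               80, seed = 2)
  aa <- apply(codonMatrix(a0), 1, function(x) paste(codonTable()[x],
                                                    collapse = ""))
  expect_true(all(aa == aa[[1]]))
  expect_error(simulateCodonAlignment(st, list(kappa = -1, pi = pi,
                                               omega = 0.5), 10))
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  st <- defaultSpeciesTree()
  p <- list(kappa = 2.5, pi = equalCodonFrequencies(), omega = 0.3)
  a1 <- simulateCodonAlignment(st, p, 40, seed = 99)
  a2 <- simulateCodonAlignment(st, p, 40, seed = 99)
  expect_identical(as.character(a1@aln), as.character(a2@aln))
  expect_identical(attr(a1, "siteClasses"), attr(a2, "siteClasses"))
})

test_that("simulated root frequencies match pi", {
  st0 <- defaultSpeciesTree(branchLengths = rep(0, 7))
  pi <- equalCodonFrequencies()
  a <- simulateCodonAlignment(st0, list(kappa = 2, pi = pi, omega = 1),
                              1e5, seed = 3)
  counts <- table(factor(codonMatrix(a)[1, ], levels = senseCodons()))
  gof <- chisq.test(as.numeric(counts), p = pi)
  expect_gt(gof$p.value, 0.01)
})

test_that("divergence scales linearly with branch length", {
  set.seed(4)
  pi <- equalCodonFrequencies()
  ts <- c(0.05, 0.2, 0.4, 0.7, 1)
  est <- vapply(ts, function(t) {
    tt <- readSpeciesTree(sprintf("(A:%f,B:%f);", t / 2, t / 2))
    a <- simulateCodonAlignment(tt, list(kappa = 1, pi = pi, omega = 1),
                                6000)
    m <- codonMatrix(a)
    ng <- ng86Pairwise(paste(m[1, ], collapse = ""),
                       paste(m[2, ], collapse = ""))
    # expected substitutions per codon from the counting estimate
    (ng$Ka * ng$N + ng$Ks * ng$S) / 6000
  }, numeric(1))
  slope <- coef(lm(est ~ 0 + ts))[[1]]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("counting estimates on simulated pairs behave as NG86 should", {
  pi <- equalCodonFrequencies()
  tt <- readSpeciesTree("(A:0.25,B:0.25);")
  ngOf <- function(kappa, n, seed) {
    a <- simulateCodonAlignment(tt, list(kappa = kappa, pi = pi, omega = 1),
                                n, seed = seed)
    m <- codonMatrix(a)
    ng86Pairwise(paste(m[1, ], collapse = ""), paste(m[2, ], collapse = ""))
  }
  # without transition bias the neutral estimate is unbiased
  expect_lt(abs(ngOf(1, 20000, 13)$omega - 1), 0.1)
  # with kappa = 2 NG86's equal-weighting of sites undercounts synonymous
  # opportunity: the known downward bias lands near 0.85
  expect_lt(abs(ngOf(2, 20000, 14)$omega - 0.85), 0.1)
})

test_that("ortholog study uses a deterministic selection quota", {
  cfg <- simulationConfig(nGenes = 40L, nCodonsRange = c(30L, 40L),
                          psgFraction = 0.2, nTerms = 6L,
                          termSizeRange = c(5L, 10L), seed = 5L)
  study <- generateOrthologStudy(cfg)
  expect_equal(sum(study$truth$selected), floor(0.2 * 40))
  expect_identical(sort(unique(study$truth$gene_id)), sort(study$truth$gene_id))
  expect_true(all(nchar(study$truth$terms) > 0))    # every gene annotated
  # psgFraction 0 leaves nothing selected
  study0 <- generateOrthologStudy(
    simulationConfig(nGenes = 10L, nCodonsRange = c(30L, 30L),
                     psgFraction = 0, nTerms = 3L,
                     termSizeRange = c(3L, 5L), seed = 6L))
  expect_equal(sum(study0$truth$selected), 0)
  # n_genes = 0: empty but well-formed
  e <- generateOrthologStudy(
    simulationConfig(nGenes = 0L, nCodonsRange = c(30L, 30L),
                     nTerms = 3L, termSizeRange = c(3L, 5L), seed = 1L))
  expect_equal(nrow(e$truth), 0)
  expect_length(e$alignments, 0)
})

test_that("identical seeds give byte-identical study files", {
  cfg <- simulationConfig(nGenes = 5L, nCodonsRange = c(30L, 40L),
                          nTerms = 4L, termSizeRange = c(2L, 4L), seed = 11L)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  generateOrthologStudy(cfg, dir = d1)
  generateOrthologStudy(cfg, dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("transcript decoys honour their divergence knobs", {
  set.seed(12)
  cds <- vapply(1:3, function(i) randomCds(80), character(1))
  names(cds) <- paste0("c", 1:3)
  # zero divergence, no fragmentation: paralog copy equals the source
  d0 <- makeTranscriptDecoys(cds, paralogDivergence = 0, fragmentation = 0,
                             seed = 2, nRandom = 1)
  expect_identical(as.character(d0$transcripts[["par_c1"]]), unname(cds["c1"]))
  # manifest labels partition the output
  expect_setequal(d0$manifest$transcript_id, names(d0$transcripts))
  expect_setequal(unique(d0$manifest$label),
                  c("ortholog", "paralog", "random"))
  expect_error(makeTranscriptDecoys(cds, fragmentation = 1.5))
})
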