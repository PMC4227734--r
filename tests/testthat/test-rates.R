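test_that("concatenation preserves the MLE and validates taxa", {
  st <- defaultSpeciesTree()
  pi <- equalCodonFrequencies()
  a <- simulateCodonAlignment(st, list(kappa = 2, pi = pi, omega = 0.25),
                              250, seed = 51, geneId = "g1")
  single <- concatenateAndFit(list(a), st, pi = "equal")
  doubled <- concatenateAndFit(list(a, a), st, pi = "equal")
  expect_equal(doubled$omega, single$omega, tolerance = 1e-3)
  expect_equal(doubled$Ka, single$Ka, tolerance = 1e-4)
  bad <- CodonAlignment(c(x = "ATG", y = "ATG"), geneId = "odd")
  expect_error(concatenateAlignments(list(a, bad)), "odd")
})

test_that("concatenated fit recovers a lineage rate contrast", {
  # foreground terminal evolves with omega 0.5, everything else 0.15:
  # the summary must order the two focal lineages correctly
  pi <- equalCodonFrequencies()
  st <- defaultSpeciesTree()
  ns <- asNamespace("CodonScan")
  cls <- data.frame(proportion = 1, background = 0.15, foreground = 0.5)
  set.seed(52)
  alns <- lapply(1:10, function(i)
    simulateCodonAlignment(st, list(kappa = 2.5, pi = pi, classes = cls),
                           200, geneId = sprintf("g%02d", i)))
  summ <- concatenateAndFit(alns, st, pi = "equal")
  expect_gt(summ$omega[summ$lineage == "vlangalii"],
            summ$omega[summ$lineage == "przewalskii"])
})

test_that("Holm adjustment matches its closed form", {
  expect_equal(holmAdjust(0.03), 0.03)
  expect_equal(holmAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holmAdjust(rep(1, 5)), rep(1, 5))
  set.seed(53)
  p <- runif(20)
  expect_equal(holmAdjust(p), holmOracle(p))
  expect_true(all(holmAdjust(p) >= p))
  expect_error(holmAdjust(c(0.5, 1.2)))
})

test_that("category binomial test matches enumeration and the >20 rule", {
  # symmetric counts with p0 = 0.5 give p = 1
  genes <- sprintf("g%03d", 1:60)
  rates <- data.frame(gene_id = genes, nA = rep(1, 60), nB = rep(1, 60))
  anno <- data.frame(gene_id = rep(genes[1:30], 2),
                     term_id = rep(c("t1", "t2"), each = 30))
  res <- categoryRateTest(anno, rates, minGenes = 21)
  expect_true(all(res$p_raw == 1))
  # a term with exactly 20 members is excluded
  anno20 <- data.frame(gene_id = genes[1:20], term_id = "small")
  res20 <- categoryRateTest(rbind(anno, anno20), rates, minGenes = 21)
  expect_false("small" %in% res20$term_id)
  expect_true("small" %in% attr(res20, "dropped"))
  # exact two-sided binomial against enumeration: n_A = 15, n_B = 5
  rates2 <- data.frame(gene_id = genes,
                       nA = c(rep(15 / 25, 25), rep(0.5, 35)),
                       nB = c(rep(5 / 25, 25), rep(0.5, 35)))
  # make genome totals symmetric so p0 = 0.5
  tot <- sum(rates2$nA) - sum(rates2$nB)
  rates2$nB[35] <- rates2$nB[35] + tot
  anno2 <- data.frame(gene_id = genes[1:25], term_id = "hot")
  res2 <- categoryRateTest(anno2, rates2, minGenes = 21)
  expect_equal(res2$p_raw, binomTwoSidedOracle(15, 20, 0.5),
               tolerance = 1e-10)
  expect_equal(res2$accelerated_lineage, "A")
})

test_that("category test is symmetric under lineage swap", {
  set.seed(54)
  genes <- sprintf("g%03d", 1:80)
  rates <- data.frame(gene_id = genes, nA = rpois(80, 4) + 0.3,
                      nB = rpois(80, 5) + 0.3)
  anno <- data.frame(gene_id = c(genes[1:25], genes[20:50], genes),
                     term_id = c(rep("t1", 25), rep("t2", 31),
                                 rep("t3", 80)))
  fwd <- categoryRateTest(anno, rates, lineages = c("A", "B"))
  swapped <- categoryRateTest(anno,
                              data.frame(gene_id = genes, nA = rates$nB,
                                         nB = rates$nA),
                              lineages = c("B", "A"))
  expect_equal(fwd$p_raw, swapped$p_raw, tolerance = 1e-12)
  expect_identical(fwd$accelerated_lineage, swapped$accelerated_lineage)
  # totals conservation: member counts re-derivable from the gene table
  for (i in seq_len(nrow(fwd))) {
    g <- unique(anno$gene_id[anno$term_id == fwd$term_id[i]])
    expect_equal(fwd$nA[i], round(sum(rates$nA[rates$gene_id %in% g])))
  }
})

test_that("familywise error is controlled under a null category study", {
  set.seed(55)
  genes <- sprintf("g%04d", 1:600)
  rates <- data.frame(gene_id = genes, nA = rpois(600, 3) + 0.2,
                      nB = rpois(600, 3) + 0.2)
  anno <- do.call(rbind, lapply(1:200, function(tm)
    data.frame(gene_id = sample(genes, 25),
               term_id = sprintf("t%03d", tm))))
  res <- categoryRateTest(anno, rates, minGenes = 21)
  expect_equal(nrow(res), 200)
  expect_lte(mean(res$p_holm < 0.05), 0.05)
  expect_true(all(res$p_holm >= res$p_raw))
})
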