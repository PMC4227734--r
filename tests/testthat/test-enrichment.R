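test_that("hypergeometric and EASE p-values match enumeration", {
  genes <- sprintf("g%02d", 1:40)
  psg <- genes[1:10]
  anno <- rbind(data.frame(gene_id = genes[c(1:4, 15:20)], term_id = "t1"),
                data.frame(gene_id = genes, term_id = "all"),
                data.frame(gene_id = genes[30:33], term_id = "none"))
  res <- fisherOverrepresentation(psg, genes, anno, mode = "ease")
  r1 <- res[res$term_id == "t1", ]
  expect_equal(r1$p_fisher, hyperTailOracle(4, 10, 10, 40),
               tolerance = 1e-12)
  expect_equal(r1$p_ease, hyperTailOracle(3, 10, 10, 40), tolerance = 1e-12)
  # a term annotating every background gene is uninformative
  expect_equal(res$p_fisher[res$term_id == "all"], 1)
  # zero overlap: EASE floors k-1 at 0
  expect_equal(res$p_ease[res$term_id == "none"], 1)
  expect_error(fisherOverrepresentation(c("zz"), genes, anno))
})

test_that("EASE is uniformly conservative relative to Fisher", {
  set.seed(61)
  for (i in 1:40) {
    N <- sample(10:50, 1)
    genes <- sprintf("g%03d", seq_len(N))
    n <- sample(2:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    anno <- data.frame(gene_id = sample(genes, K), term_id = "t")
    res <- fisherOverrepresentation(sample(genes, n), genes, anno)
    expect_gte(res$p_ease, res$p_fisher)
    expect_equal(res$p_fisher, hyperTailOracle(res$k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("empty PSG list yields all-ones", {
  genes <- sprintf("g%02d", 1:10)
  anno <- data.frame(gene_id = genes[1:5], term_id = "t")
  res <- fisherOverrepresentation(character(0), genes, anno)
  expect_true(all(res$p == 1))
})

test_that("enrichment scores follow the geometric-mean arithmetic", {
  expect_equal(enrichmentScore(c(1, 1, 1)), 0)
  expect_equal(enrichmentScore(c(0.05, 0.05)), 1.30103, tolerance = 1e-5)
  expect_equal(enrichmentScore(c(0.1, 0.001)), 2)
  # permutation-invariant and monotone decreasing in each p
  p <- c(0.2, 0.01, 0.6)
  expect_equal(enrichmentScore(p), enrichmentScore(rev(p)))
  expect_gt(enrichmentScore(c(0.1, 0.01)), enrichmentScore(c(0.1, 0.02)))
  expect_warning(es0 <- enrichmentScore(c(0, 0.1)))
  expect_true(is.finite(es0))
  expect_error(enrichmentScore(c(0.5, 1.2)))
})

test_that("classification applies the strict ES and p thresholds", {
  res <- data.frame(term_id = c("a", "b", "c"),
                    k = 3, n = 10, K = 5, N = 100,
                    p_fisher = c(10^-1.3, 0.032, 0.06),
                    p_ease = c(10^-1.3, 0.032, 0.06),
                    p = c(10^-1.3, 0.032, 0.06),
                    p_adjust = c(0.1, 0.1, 0.1),
                    genes = "")
  out <- classifyOverRepresented(res)
  # ES exactly 1.3 is not greater than 1.3
  expect_false(out$over_represented[out$term_id == "a"])
  # ES 1.49 with p 0.032 passes (the Table-2-style row: ES 2.8, p 0.032,
  # would likewise pass)
  expect_true(out$over_represented[out$term_id == "b"])
  expect_false(out$over_represented[out$term_id == "c"])  # p too large
  # user-supplied clusters pool the member p-values
  cl <- classifyOverRepresented(res, clusters = list(grp = c("a", "b")))
  expect_equal(cl$ES[cl$term_id == "a"],
               enrichmentScore(c(10^-1.3, 0.032)), tolerance = 1e-10)
  expect_equal(cl$cluster[cl$term_id %in% c("a", "b")], c("grp", "grp"))
})

test_that("null PSG draws reject near or below the nominal rate", {
  set.seed(62)
  genes <- sprintf("g%04d", 1:500)
  anno <- do.call(rbind, lapply(1:60, function(tm)
    data.frame(gene_id = sample(genes, 30),
               term_id = sprintf("t%02d", tm))))
  fracs <- replicate(30, {
    res <- fisherOverrepresentation(sample(genes, 50), genes, anno)
    mean(res$p < 0.05)
  })
  # one-tailed discrete p: at or below alpha up to binomial noise
  expect_lte(mean(fracs), 0.07)
})
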