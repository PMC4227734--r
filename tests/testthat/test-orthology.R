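test_that("translated similarity recovers identity and strand symmetry", {
  ns <- asNamespace("CodonScan")
  set.seed(21)
  cds <- randomCds(50)
  hit <- translatedSimilarity(cds, cds)
  expect_equal(hit$queryFrame, 1L)
  # self-score equals the sum of diagonal BLOSUM62 entries of the peptide
  sc <- ns$.defaultScoring()
  pep <- strsplit(ns$.translateFrame(cds, 1L), "")[[1]]
  expect_equal(hit$score, sum(diag(sc$matrix[pep, pep])))
  expect_equal(hit$queryRange, c(0, 150))
  # reverse complement: same peptide score on the negative strand
  rc <- ns$.revComp(cds)
  hit2 <- translatedSimilarity(rc, cds)
  expect_equal(hit2$score, hit$score)
  expect_lt(hit2$queryFrame, 0)
  expect_error(translatedSimilarity("AT", cds))
})

test_that("similarity scores match an exhaustive DP oracle", {
  ns <- asNamespace("CodonScan")
  sc <- ns$.defaultScoring()
  set.seed(22)
  # the documented case: 30 codons, 3 amino-acid differences
  a <- randomCds(30)
  pepA <- ns$.translateFrame(a, 1L)
  b <- a
  for (p in c(4, 12, 25)) {
    repeat {
      cand <- senseCodons()[sample.int(61, 1)]
      if (codonTable()[cand] != codonTable()[substr(b, 3 * p - 2, 3 * p)]) {
        substr(b, 3 * p - 2, 3 * p) <- cand
        break
      }
    }
  }
  hit <- translatedSimilarity(a, b)
  oracle <- swOracle(pepA, ns$.translateFrame(b, 1L), sc$matrix, 11, 1)
  expect_equal(hit$score, oracle)
  # random unrelated pairs, all frames
  for (i in 1:5) {
    x <- randomCds(25); y <- randomCds(35)
    hit <- translatedSimilarity(x, y)
    frames <- expand.grid(qf = c(1:3, -(1:3)), tf = 1:3)
    best <- max(apply(frames, 1, function(fr)
      swOracle(ns$.translateFrame(x, fr[1]), ns$.translateFrame(y, fr[2]),
               sc$matrix, 11, 1)))
    expect_equal(hit$score, best)
  }
})

test_that("reciprocal best hits keep only unambiguous 1:1 pairs", {
  set.seed(23)
  x <- randomCds(60); y <- randomCds(60)
  # exact copy pairs with an unrelated partner
  brh <- bestReciprocalHits(c(t1 = x, t2 = randomCds(60)),
                            c(r1 = x, r2 = y))
  expect_true(any(brh$transcript_id == "t1" & brh$cds_id == "r1"))
  expect_false(any(brh$transcript_id == "t2"))   # random: below threshold
  # tie for the best hit drops the transcript
  brhTie <- bestReciprocalHits(c(t1 = x), c(r1 = x, r2 = x))
  expect_equal(nrow(brhTie), 0)
  expect_true("t1" %in% attr(brhTie, "dropped"))
  # reciprocity violated: r1's best is t0, so t1 gets nothing
  brhRec <- bestReciprocalHits(c(t0 = x, t1 = paste0(x, randomCds(30))),
                               c(r1 = x))
  expect_true(all(brhRec$transcript_id != "t1"))
  expect_error(bestReciprocalHits(character(0), c(r = x)))
})

test_that("raising the score threshold never adds pairs", {
  set.seed(24)
  cds <- vapply(1:5, function(i) randomCds(70), character(1))
  names(cds) <- paste0("c", 1:5)
  d <- makeTranscriptDecoys(cds, paralogDivergence = 1, fragmentation = 0.2,
                            seed = 3, nRandom = 2)
  prev <- NULL
  for (ms in c(40, 80, 160, 320)) {
    got <- bestReciprocalHits(d$transcripts, cds, minScore = ms)
    keys <- paste(got$transcript_id, got$cds_id)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("BRH separates orthologs from diverged paralogs at scale", {
  set.seed(25)
  nFam <- 50
  cds <- vapply(seq_len(nFam), function(i) randomCds(90), character(1))
  names(cds) <- sprintf("c%03d", seq_len(nFam))
  d <- makeTranscriptDecoys(cds, paralogDivergence = 2, fragmentation = 0.3,
                            seed = 4, nRandom = 10)
  brh <- bestReciprocalHits(d$transcripts, cds)
  truth <- d$manifest[d$manifest$label == "ortholog", ]
  hits <- merge(brh, truth, by.x = "transcript_id", by.y = "transcript_id")
  correct <- sum(hits$cds_id == hits$source_cds)
  expect_gte(correct / nFam, 0.95)
  # paralogs and random sequences must not appear in the pairing
  lab <- d$manifest$label[match(brh$transcript_id, d$manifest$transcript_id)]
  expect_true(all(lab == "ortholog"))
})
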