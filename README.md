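# CodonScan

Branch-site scans for positive selection in comparative transcriptomes.

CodonScan is an R package for the classic comparative-genomics question:
*which genes changed under positive selection on one particular lineage?*
It was built around the study design used for high-elevation adaptation in
toad-headed lizards — two *Phrynocephalus* transcriptomes compared against
anole, chicken and softshell turtle on a fixed five-taxon phylogeny — but
every stage is generic:

* **Orthology** — 1:1 ortholog calls by best reciprocal hit, using a
  six-frame × three-frame translated Smith–Waterman search (BLOSUM62,
  affine gaps, stop codons forbidden) with a shuffle-calibrated score
  threshold.
* **Alignment QC** — read-support consensus calling, a codon-mode block
  trimmer, stop-codon and 200 bp length filters, and a substitution-
  saturation screen that fits GTR branch lengths to third codon positions
  and discards genes with any branch ≥ 1.
* **Selection scan** — branch-site codon model A versus its ω₂ = 1 null,
  maximized by a staged quasi-Newton scheme over a compiled pruning
  engine; genes with LRT *p* < 0.05 on the foreground branch are PSGs.
* **Lineage rates** — free-ratio fits (one ω per branch) giving per-branch
  Ka, Ks and expected substitution counts; lineage means from the
  concatenated super-alignment; a category-level exact binomial test with
  Holm correction for accelerated evolution (categories need > 20
  orthologs).
* **Enrichment** — hypergeometric / EASE over-representation of the PSG
  list, geometric-mean enrichment scores, and the ES > 1.3 & *p* < 0.05
  classification rule.
* **Synthetic studies** — a codon-evolution simulator with known truth
  (selected-gene quotas, planted enriched terms, decoy paralogs) so the
  whole chain is testable without any downloads.

The core model is the Goldman–Yang codon process: for single-nucleotide
codon changes, q_ij ∝ π_j · {1, κ, ω, ωκ} for synonymous/nonsynonymous ×
transversion/transition, scaled to one expected substitution per codon
per unit branch length. The branch-site alternative adds site classes
2a/2b whose ω₂ ≥ 1 applies only on the flagged foreground branch; the
statistic 2Δℓ is referred to χ²₁ (conservative). Per branch,
Ka/Ks ≡ ω by the mutational-opportunity site convention.

## Worked example

Simulate a small study (20 genes, 25% carrying foreground ω₂ = 5), run
the whole pipeline, and look at the scan:

```r
library(CodonScan)
cfg <- runConfig(
  sim = simulationConfig(nGenes = 20L, nCodonsRange = c(150L, 300L),
                         psgFraction = 0.25, foregroundOmega2 = 5,
                         nTerms = 5L, termSizeRange = c(6L, 10L), seed = 42L),
  outdir = "readme_run", minCategoryOrthologs = 6)
res <- runPipeline(cfg)
unlist(res$summary$counts)
#>         simulated      after_filter  after_saturation           scanned
#>                20                20                20                20
#>              psgs categories_tested     terms_flagged
#>                 1                 5                 0
head(res$scan[order(res$scan$p_value),
              c("gene_id", "lrt", "p_value", "omega2", "psg_flag")], 3)
#>      gene_id   lrt p_value omega2 psg_flag
#> 17 gene_0017 5.614  0.0178  10.42     TRUE
#> 1  gene_0001 3.830  0.0503   9.89    FALSE
#> 4  gene_0004 1.922  0.1657   9.54    FALSE
res$lineages
#>       lineage      t omega     Ka     Ks
#> 1   vlangalii 0.1075 0.585 0.0296 0.0507
#> 2 przewalskii 0.0851 0.399 0.0196 0.0493
```

Every simulated gene passes QC (no saturation at these branch lengths);
one of the five planted selection genes is significant at these short
gene lengths (`psg_recall` 0.2 against the truth table, precision 1) —
power rises quickly with ω₂ and alignment length, which the acceptance
suite quantifies at 500 codons. The lineage table is the free-ratio fit
of the concatenated alignment: the foreground lineage shows the elevated
Ka/Ks its simulation settings planted. A single gene's test looks like:

```r
study <- generateOrthologStudy(cfg$sim)   # same seed: same alignments
fit <- fitBranchSite(study$alignments[["gene_0002"]], cfg$sim@tree)
fit
#> BranchSiteFit 'gene_0002'
#>   lnL alt/null: -1958.8748 / -1959.1735
#>   2*dlnL = 0.5975, p = 0.4395
#>   omega0 = 0.075, omega2 = 2.562, p0 = 0.315, p1 = 0.526
```

The Sanger-concordance utility reproduces the published worked
percentages from their printed totals:

```r
percentConsistency(2799, 12)   # 99.57
percentConsistency(4485, 3)    # 99.93
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/codonscan-cli.R`
(`Rscript codonscan-cli.R all --config cfg.json`).

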