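Package: CodonScan
Title: Branch-Site Scans for Positive Selection in Comparative Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for lineage-specific scans of positive
    selection from comparative transcriptome data: reciprocal-best-hit
    orthology by translated local alignment, codon-alignment quality control
    with a third-position GTR substitution-saturation screen, branch-site
    codon-model likelihood-ratio tests for positively selected genes on a
    designated foreground lineage, free-ratio per-branch Ka/Ks estimation
    with a category-level binomial test for accelerated evolution, and
    over-representation scoring of selected genes in functional categories.
    A codon-evolution simulator generates ortholog studies with known truth
    so every stage has a parameter-recovery test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix
Config/testthat/edition: 3
biocViews: Phylogenetics, SequenceAnalysis, Software
RoxygenNote: 7.3.3
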