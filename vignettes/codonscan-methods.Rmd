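---
title: "Methods: branch-site selection scans in CodonScan"
author: "CodonScan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-site selection scans in CodonScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CodonScan re-implements, as a tested and reusable pipeline, the
comparative-transcriptomics workflow used to look for positively selected
genes (PSGs) on a single high-elevation lizard lineage within a fixed
five-taxon amniote phylogeny: orthology calls by best reciprocal hit,
codon-alignment quality control with a substitution-saturation screen,
branch-site likelihood-ratio tests, free-ratio Ka/Ks comparisons with a
category-level binomial test, and over-representation scoring of the PSG
list. This vignette records the models, the numerical design, and the
choices made where the underlying procedure left room for judgement.

## The codon substitution model

All likelihood machinery rests on the Goldman–Yang codon process on the 61
sense codons. For codons $i \neq j$ differing at exactly one position,

$$ q_{ij} \propto \pi_j \times \begin{cases}
1 & \text{synonymous transversion} \\
\kappa & \text{synonymous transition} \\
\omega & \text{nonsynonymous transversion} \\
\omega\kappa & \text{nonsynonymous transition,}
\end{cases} $$

with all other off-diagonal rates zero (multi-step changes and changes
through stop codons are forbidden). The generator is scaled so one unit of
branch length is one expected substitution per codon at stationarity.
Codon frequencies $\pi$ default to an F3x4-style product of
position-specific nucleotide frequencies estimated from the alignment
(`f3x4Frequencies()`); an equal-frequency option exists for controlled
experiments. The standard nuclear genetic code is hard-coded; gap codons
and codons containing ambiguity characters are treated as missing data
and marginalized in the pruning recursion.

Transition matrices come from the symmetrized eigendecomposition of the
reversible generator ($P(t) = \Pi^{-1/2} V e^{\Lambda t} V' \Pi^{1/2}$),
and tree likelihoods from Felsenstein pruning over compressed site
patterns, both in compiled code. Reversibility makes the likelihood
independent of the rooting of the unrooted tree, which the tests verify.

**Shared scaling across site classes.** In mixture models the site
classes share one scale factor rather than being normalized class by
class. A site from a class with a larger $\omega$ therefore substitutes
*faster*, not merely with a different synonymous/nonsynonymous split.
Concretely, simulation interprets a branch length as the expected number
of substitutions per codon for a site drawn from the class mixture on a
background branch; the fitting code parameterizes lengths in neutral
($\omega = 1$) units internally, which is the same model family under a
reparameterization. Without a shared scale the foreground signal of the
branch-site model all but disappears, because extra nonsynonymous
substitutions would be compensated by a reduced overall rate.

## The branch-site test

`fitBranchSite()` fits branch-site model A: site classes 0 and 1 evolve
with $\omega_0 \in (0,1)$ and $\omega = 1$ everywhere; classes 2a and 2b
switch to $\omega_2 \ge 1$ on the designated foreground branch. Class
proportions carry the model's product structure
$(p_0, p_1, p_{2a}, p_{2b}) = (qP,\,(1-q)P,\,q(1-P),\,(1-q)(1-P))$ with
$P = p_0 + p_1$, so $p_{2a}:p_{2b} = p_0:p_1$ automatically. The null
model is identical with $\omega_2 = 1$. The LRT statistic
$2\Delta\ell$ is clamped at zero and referred to $\chi^2_1$ — the
deliberately conservative convention for this boundary problem — and a
gene is called a PSG when $p < 0.05$ (strict).

**Optimization design.** A full joint search over all branch lengths for
every gene and both models is the main cost of a genome-scale scan. The
package stages it:

1. A one-ratio (M0) fit estimates $\kappa$, a global $\omega$, and all
   branch lengths by cyclic coordinate ascent (Brent per branch across a
   conditional-likelihood decomposition of the tree at that branch,
   quasi-Newton for $\kappa, \omega$).
2. Both branch-site models then keep $\kappa$ and the *relative*
   background branch lengths from M0 and maximize, by bounded
   quasi-Newton (L-BFGS-B on log scales), the free parameters
   $(\omega_0, [\omega_2], c, t_{fg})$: a single scale factor $c$ on the
   background lengths and the foreground branch length itself, which is
   the length the foreground hypothesis directly concerns. For each
   candidate, the class weights $(q, P)$ are profiled out exactly by an
   inner 2-parameter quasi-Newton step with analytic gradients.
3. Three deterministic starts are screened (a cheap $\omega_2$ grid seeds
   the alternative), the best is polished, and the null is re-polished
   from the alternative's optimum so that an under-optimized null can
   never inflate the statistic.

The decomposition across the foreground edge means an objective
evaluation costs roughly one pruning pass (the $\omega = 1$ pass and the
foreground-edge transition matrices are cached), which is what makes
200-gene calibration studies run in minutes. Convergence tolerances:
$10^{-8}$ (relative, on the log-likelihood) for the outer quasi-Newton,
$10^{-12}$ for the inner weight profile; branch lengths are bounded in
$[10^{-9}, 20]$, $\omega_0 \in [10^{-4}, 1)$, $\omega_2 \in [1, 999]$.
Fixing $\kappa$ and the internal branch-length proportions at their M0
estimates is a deliberate trade: both models share the same values, so
the comparison stays fair, and the null-calibration test (below) checks
that the resulting LRT is not anticonservative.

## Free-ratio rates and Ka/Ks

`fitFreeRatio()` gives every branch its own $(t_b, \omega_b)$ with a
shared $\kappa$, maximized by cyclic per-branch 2-parameter quasi-Newton
steps using the same edge decomposition, with $\kappa$ line searches
between sweeps. Synonymous and nonsynonymous site proportions follow the
mutational-opportunity convention (the flux split of the process with
$\omega$ forced to 1), so that per branch

$$ K_a = \frac{t_b\,a_N(\omega_b)}{3\rho_N}, \qquad
   K_s = \frac{t_b\,a_S(\omega_b)}{3\rho_S}, \qquad
   \frac{K_a}{K_s} \equiv \omega_b, $$

exactly, where $a_N, a_S$ are the flux shares at $\omega_b$ and
$\rho_N, \rho_S$ the site proportions. Expected substitution counts per
gene ($\hat n = t_b a_N L$, $\hat s = t_b a_S L$ for $L$ codons) feed the
category-level binomial test. Zero-length branches report $\omega$ as
undefined with zero rates. Two-taxon alignments are handled as a single
branch. `ng86Pairwise()` provides the independent counting cross-check
(Nei–Gojobori site counting with Jukes–Cantor correction, pathways
averaged for multi-position codon differences, stops counted as
nonsynonymous, proportions $\ge 0.75$ reported as undefined).

Lineage-level "mean" rates are taken from one free-ratio fit of the
concatenated super-alignment — not from averaging per-gene estimates, and
the reported mean Ka/Ks is the concatenated fit's branch $\omega$, not a
ratio of means. The category-level comparison sums each category's
expected nonsynonymous counts on the two focal lineages (rounded
half-even from their fractional expectations), tests the lineage-A share
against the genome-wide proportion with a two-sided exact binomial test,
requires strictly more than 20 member orthologs, and applies the Holm
step-down correction across categories.

## Orthology by best reciprocal hit

Translated similarity is a six-frame (query) by three-frame (target)
local alignment of the translated peptides under BLOSUM62 with affine
gaps (open 11, extend 1); stop codons carry a large negative score so
frames with internal stops cannot win, which mimics the behaviour of a
translated BLAST search without reproducing its e-value statistics.
Significance is a raw-score threshold instead: the default of 60 clears
the 99.999th percentile of shuffled-sequence null scores (see
`calibrateScoreThreshold()`) by a wide margin for CDS-sized sequences.
A pair is reported only when each sequence is the *unique* top-scoring
hit of the other, both scores reach the threshold, and the aligned region
covers at least 30% of the shorter translated length; ties are dropped,
keeping only unambiguous 1:1 orthologs. Coordinates are 0-based,
half-open, on the input nucleotide strings, with strand in the sign of
the frame.

## Alignment QC and the saturation screen

Consensus calling takes the base with the most mapped reads, `N` on zero
support, and breaks ties alphabetically (A < C < G < T) — a deterministic
documented rule. The block trimmer is a simplified codon-mode filter: a
column is kept when its gap fraction is at most `maxGapFraction`
(default 0) and at least half of the taxa share the majority amino acid,
and only runs of at least `minBlock = 5` consecutive good columns
survive. This is deliberately a surrogate for heavier trimming tools, not
a re-implementation; on clean simulated alignments it removes roughly the
neutral columns where five diverged taxa disagree, which the test
fixtures account for. The length/stop filter then discards genes with
any stop codon or a trimmed length under 200 bp (a 67-codon alignment at
201 bp survives; 66 codons at 198 bp does not; the boundary stays at
exactly 200).

One consequence of the surrogate rule deserves emphasis: on *exact*
simulated alignments — which contain no misalignment, no gaps and no
unreliable regions — the majority-residue criterion preferentially
removes the very columns where divergence concentrates, including the
foreground-selected sites the branch-site test looks for. Measured on
simulated 300–500-codon genes, trimming cuts the test's power roughly
from 0.8 to 0.35. Trimming exists to remove alignment artefacts, and
simulated data have none, so the pipeline exposes the trim step as a
stage toggle and the package's synthetic end-to-end studies run with it
disabled; for real alignments it stays on by default.

The saturation screen extracts third codon positions and fits GTR branch
lengths on the fixed topology by maximum likelihood — empirical base
frequencies, five free exchangeabilities (GT fixed at 1), all branch
lengths free, three deterministic starts of bounded quasi-Newton on log
scale, lengths bounded in $[10^{-8}, 50]$. A gene is called saturated
when any fitted branch length reaches 1.0; optimizer failure on all
starts flags the gene saturated, conservatively. Whether the original
screen estimated GTR parameters per gene or globally is not recorded
anywhere; CodonScan fits per gene and says so.

## Enrichment

Over-representation uses the one-tailed hypergeometric upper tail; the
default "EASE" mode removes one success before computing the tail, which
is uniformly conservative ($p_{EASE} \ge p_{Fisher}$, with $k = 0$ giving
$p = 1$). Benjamini–Hochberg adjusted values are reported alongside the
raw p-values; classification follows the published rule on the raw
(EASE) p, as the corresponding results table does. The enrichment score
of a category is $-\log_{10}$ of the geometric mean of its term
p-values; with the default one-term-per-cluster setting this reduces to
$-\log_{10} p$. A category is over-represented iff ES is strictly
greater than 1.3 *and* p is strictly below 0.05. Term clustering itself
(a fuzzy similarity heuristic in the original annotation service) is out
of scope; user-supplied cluster memberships are accepted instead.

## The synthetic study generator

`generateOrthologStudy()` is the test bed that stands in for the real
transcriptome dataset. Its defaults are the package's standing study
conditions:

* the five-taxon unrooted topology with the high-elevation terminal as
  foreground; branch lengths (in substitutions per codon) of 0.1 for the
  two focal terminals, 0.45–0.5 for the three deep amniote branches and
  0.1–0.15 for the internals — no published lengths exist for this tree,
  so these are realistic round numbers chosen once: modest divergence
  between the sister species, deep but unsaturated outgroups;
* $\kappa = 2.5$ (a typical vertebrate transition bias),
  $\omega_0 = 0.15$ (matching the strongly purifying genome-wide
  averages reported for these lineages), $p_0 = p_1 = 0.4$ so that 20%
  of sites fall into the foreground classes;
* $\omega_2 = 5$ on a deterministic quota of
  $\lfloor 0.2\,n \rfloor$ genes (first indices after a seeded shuffle —
  exact truth counts for tests), $\omega_2 = 1$ on the rest;
* gene lengths uniform on 150–450 codons; annotation terms of 25–40
  genes, two of them drawing 60% of their members from the selected
  genes so enrichment has a planted signal; every gene gets at least one
  term.

Decoy transcript sets add UTR-like random flanks, optional truncation,
paralogs evolved by an extra branch length of 2 substitutions per codon
(about 60% nucleotide identity) and unrelated random sequences, with a
manifest of true labels for scoring the BRH stage.

What the generator deliberately does **not** emulate: sequencing error,
assembly chimerism and fragmented isoforms beyond simple truncation,
alignment error (the pipeline consumes aligned codons), indels, rate
variation beyond the branch-site classes, GO-graph structure (annotations
are flat labels), and expression levels. Passing tests therefore
demonstrate correctness of the statistical machinery under the model's
own assumptions, not robustness to the full messiness of transcriptome
assemblies.

## Test problem sizes

The automated suite exercises the chain at sizes chosen to give the
statistical checks reasonable resolution while keeping a full run on one
CPU in the tens of minutes: 200 genes of 150 codons for the null
calibration of the LRT (empirical rejection at $\alpha = 0.05$ must stay
at or below 0.07), 50 genes of 500 codons for power against
$\omega_2 = 5$ (at least 70% rejections), two-taxon alignments of
20,000 codons at a divergence comparable to the focal species pair
($t = 0.2$, $\kappa = 2$) for free-ratio recovery at
$\omega \in \{0.2, 1, 3\}$ with the NG86 counting cross-check (NG86's
neglect of the transition bias costs it roughly 15% downward at
$\kappa = 2$, inside the 20% agreement band; at $\kappa = 2.5$ it would
not be), 50 replicates of 500 third-position sites for the saturation
screen, and an end-to-end study of 200 genes of 350–500 codons (trim
stage off, as above) for truth recovery (PSG recall at least 0.5 and at
least one planted term flagged). The
`scripts/acceptance.R` entry point recomputes the same quantities at
somewhat smaller sizes. Branch-length recovery checks for the GTR screen
compare the median per-branch error (a single branch at 2,000 sites has
sampling noise of the same order as the 15% tolerance).

## Known limitations

* Branch-site fits share $\kappa$ and relative background branch lengths
  with the one-ratio fit rather than re-maximizing every length per
  model; the calibration and power tests bound the practical effect, but
  likelihoods are slightly below the unconstrained optimum.
* The LRT's $\chi^2_1$ reference is conservative by construction; with
  very short genes (under ~100 codons) the asymptotics degrade further.
* NG86 counting saturates near corrected proportions of 0.75 and is
  biased at high $\omega$; it is a cross-check, not the estimator.
* The BRH score threshold is calibrated for CDS-scale sequences; very
  short transcripts need a recalibrated `minScore`.
* Bayes empirical Bayes identification of selected *sites* is out of
  scope, as are codon models beyond the branch-site pair and the
  free-ratio model.
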