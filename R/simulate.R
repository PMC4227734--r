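#' SimulationConfig: study conditions for a synthetic ortholog study
#'
#' Collects every knob of the codon-evolution simulator. Defaults are the
#' package's standing study conditions: the five-taxon
#' \code{\link{defaultSpeciesTree}}, kappa = 2.5, background purifying
#' omega0 = 0.15, branch-site class proportions p0 = 0.4, p1 = 0.4 (so 20%
#' of sites fall in the foreground classes 2a/2b), foreground omega2 = 5
#' on selected genes (omega2 = 1 on null genes), gene lengths drawn
#' uniformly from 150--450 codons, and 20% of genes selected by a
#' deterministic quota.
#'
#' @slot tree a \linkS4class{SpeciesTree} with foreground branch.
#' @slot nGenes number of ortholog families.
#' @slot nCodonsRange integer range (min, max) of gene lengths in codons.
#' @slot kappa transition/transversion ratio (> 0).
#' @slot backgroundOmega omega0 of the purifying site class, in (0, 1).
#' @slot psgFraction fraction of genes given foreground omega2 > 1.
#' @slot foregroundOmega2 omega2 of selected genes (>= 1).
#' @slot p0,p1 proportions of site classes 0 and 1 (classes 2a/2b take the
#'   rest split as p0:p1).
#' @slot codonFrequencies \code{"equal"} or a numeric 61-vector over the
#'   sense codons (stop codons excluded by construction).
#' @slot paralogDivergence extra branch length for decoy paralog copies.
#' @slot nTerms number of annotation terms.
#' @slot termSizeRange range of term sizes (genes per term).
#' @slot enrichedTerms number of terms biased toward selected genes.
#' @slot enrichmentBias fraction of an enriched term's members drawn from
#'   selected genes.
#' @slot seed integer seed; the same seed gives bit-identical output.
#' @export
setClass("SimulationConfig",
         representation(tree = "SpeciesTree", nGenes = "integer",
                        nCodonsRange = "integer", kappa = "numeric",
                        backgroundOmega = "numeric", psgFraction = "numeric",
                        foregroundOmega2 = "numeric", p0 = "numeric",
                        p1 = "numeric", codonFrequencies = "ANY",
                        paralogDivergence = "numeric", nTerms = "integer",
                        termSizeRange = "integer", enrichedTerms = "integer",
                        enrichmentBias = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@psgFraction < 0 || object@psgFraction > 1)
    return("psgFraction must lie in [0, 1]")
  if (object@kappa <= 0) return("kappa must be > 0")
  if (object@backgroundOmega <= 0) return("backgroundOmega must be > 0")
  if (object@foregroundOmega2 < 1) return("foregroundOmega2 must be >= 1")
  if (object@p0 + object@p1 > 1) return("p0 + p1 must be <= 1")
  if (is.numeric(object@codonFrequencies)) {
    ok <- tryCatch({ .checkCodonFrequencies(object@codonFrequencies); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
  }
  if (any(.phyloOf(object@tree)$edge.length < 0))
    return("negative branch length in tree")
  TRUE
})

#' @describeIn SimulationConfig constructor with study-condition defaults.
#' @param tree,nGenes,nCodonsRange,kappa,backgroundOmega,psgFraction
#'   see slots.
#' @param foregroundOmega2,p0,p1,codonFrequencies,paralogDivergence see slots.
#' @param nTerms,termSizeRange,enrichedTerms,enrichmentBias,seed see slots.
#' @export
simulationConfig <- function(tree = defaultSpeciesTree(), nGenes = 200L,
                             nCodonsRange = c(150L, 450L), kappa = 2.5,
                             backgroundOmega = 0.15, psgFraction = 0.2,
                             foregroundOmega2 = 5, p0 = 0.4, p1 = 0.4,
                             codonFrequencies = "equal",
                             paralogDivergence = 2, nTerms = 30L,
                             termSizeRange = c(25L, 40L),
                             enrichedTerms = 2L, enrichmentBias = 0.6,
                             seed = 1L) {
  methods::new("SimulationConfig", tree = tree, nGenes = as.integer(nGenes),
               nCodonsRange = as.integer(nCodonsRange), kappa = kappa,
               backgroundOmega = backgroundOmega, psgFraction = psgFraction,
               foregroundOmega2 = foregroundOmega2, p0 = p0, p1 = p1,
               codonFrequencies = codonFrequencies,
               paralogDivergence = paralogDivergence,
               nTerms = as.integer(nTerms),
               termSizeRange = as.integer(termSizeRange),
               enrichedTerms = as.integer(enrichedTerms),
               enrichmentBias = enrichmentBias, seed = as.integer(seed))
}

.resolvePi <- function(codonFrequencies) {
  if (is.character(codonFrequencies)) {
    if (codonFrequencies != "equal")
      stop("codonFrequencies must be 'equal' or a 61-vector")
    equalCodonFrequencies()
  } else .checkCodonFrequencies(codonFrequencies)
}

# Draw child states from parent states through P, grouped by parent state.
.evolveStates <- function(states, P) {
  out <- integer(length(states))
  for (st in unique(states)) {
    idx <- which(states == st)
    out[idx] <- sample.int(nrow(P), length(idx), replace = TRUE,
                           prob = P[st, ])
  }
  out
}

#' Simulate one codon alignment on a tree
#'
#' Sites are i.i.d. given their site class. The root codon is drawn from
#' pi and evolved along each branch by the transition matrices of the
#' scaled codon model; a site's class sets the background omega on all
#' branches and the foreground omega on the flagged branch. Uses the
#' current RNG state unless \code{seed} is given.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param params list with \code{kappa}, \code{pi} (61-vector) and
#'   \code{classes}: data.frame(proportion, background, foreground).
#'   A plain \code{omega} entry is shorthand for one class.
#' @param nCodons number of codon sites.
#' @param seed optional integer seed.
#' @param geneId gene id of the returned alignment.
#' @return a \linkS4class{CodonAlignment}; the per-site class assignment is
#'   attached as attribute \code{"siteClasses"}.
#' @export
simulateCodonAlignment <- function(tree, params, nCodons, seed = NULL,
                                   geneId = "gene") {
  if (!is.null(seed)) set.seed(seed)
  phy <- .phyloOf(tree)
  if (any(phy$edge.length < 0)) stop("negative branch length")
  kappa <- params$kappa
  pi <- .checkCodonFrequencies(params$pi)
  classes <- params$classes
  if (is.null(classes))
    classes <- data.frame(proportion = 1, background = params$omega,
                          foreground = params$omega)
  if (any(classes$background < 0) || any(classes$foreground < 0) ||
      kappa <= 0)
    stop("invalid model parameters")
  needsFg <- any(classes$background != classes$foreground)
  fgRow <- if (needsFg) {
    .foregroundEdgeRow(if (methods::is(tree, "SpeciesTree")) tree else
                         stop("foreground classes need a SpeciesTree"))
  } else 0L
  eng <- .treeEngine(phy)
  cls <- sample.int(nrow(classes), nCodons, replace = TRUE,
                    prob = classes$proportion)
  nodeStates <- matrix(0L, eng$nnodes, nCodons)
  nodeStates[eng$root, ] <- sample.int(length(pi), nCodons, replace = TRUE,
                                       prob = pi)
  # Common mixture scaling: a branch length is the expected number of
  # substitutions per codon for a site drawn from the class mixture on a
  # background branch; classes with larger omega substitute faster.
  fp <- .fluxParts(kappa, pi)
  sW <- function(w) unname(fp["fs"] + w * fp["fn"])
  sBar <- sum(classes$proportion * sW(classes$background))
  eigCache <- new.env(parent = emptyenv())
  getEig <- function(om) {
    key <- sprintf("%.12g", om)
    if (is.null(eigCache[[key]]))
      eigCache[[key]] <- .codonEigen(kappa, om, pi)
    eigCache[[key]]
  }
  # preorder: reverse of postorder edge list
  for (e in rev(seq_len(nrow(eng$edge)))) {
    par <- eng$edge[e, 1]; chl <- eng$edge[e, 2]
    isFg <- eng$orig[e] == fgRow
    for (cl in seq_len(nrow(classes))) {
      om <- if (isFg) classes$foreground[cl] else classes$background[cl]
      idx <- which(cls == cl)
      if (!length(idx)) next
      eig <- getEig(om)
      P <- cpp_pmat(eig$lambda, eig$W1, eig$W2, eng$len[e] * sW(om) / sBar)
      nodeStates[chl, idx] <- .evolveStates(nodeStates[par, idx], P)
    }
  }
  sense <- senseCodons()
  seqs <- vapply(seq_len(eng$ntaxa), function(tx) {
    paste0(sense[nodeStates[tx, ]], collapse = "")
  }, character(1))
  names(seqs) <- phy$tip.label
  out <- CodonAlignment(seqs, geneId = geneId)
  attr(out, "siteClasses") <- cls
  out
}

# Branch-site class table for a gene: proportions (p0, p1, p2a, p2b) with
# p2a:p2b = p0:p1, background omegas (omega0, 1, omega0, 1), foreground
# omegas (omega0, 1, omega2, omega2).
.branchSiteClasses <- function(p0, p1, omega0, omega2) {
  p2 <- 1 - p0 - p1
  data.frame(
    proportion = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
    background = c(omega0, 1, omega0, 1),
    foreground = c(omega0, 1, omega2, omega2))
}

#' Generate a complete synthetic ortholog study
#'
#' Simulates \code{nGenes} codon alignments on the configured tree. A
#' deterministic quota of \code{floor(psgFraction * nGenes)} genes (the
#' first indices after a seeded shuffle) is simulated with foreground
#' omega2 = \code{foregroundOmega2}; the rest use omega2 = 1. Each gene is
#' annotated with at least one term; \code{enrichedTerms} terms draw a
#' biased share of members from the selected genes so enrichment analyses
#' have a known signal. Everything is written under \code{dir}: one FASTA
#' per family (headers \code{species|gene_id}), \code{annotations.tsv},
#' \code{truth.tsv} and \code{manifest.json}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created); \code{NULL} keeps everything in
#'   memory only.
#' @return invisible list with \code{alignments} (named list),
#'   \code{truth} (data.frame), \code{annotations} (data.frame),
#'   \code{paths}.
#' @export
generateOrthologStudy <- function(config, dir = NULL) {
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nGenes
  pi <- .resolvePi(config@codonFrequencies)
  ids <- sprintf("gene_%04d", seq_len(n))
  nSel <- floor(config@psgFraction * n)
  selected <- logical(n)
  if (n > 0) selected[sample.int(n)[seq_len(nSel)]] <- TRUE
  lens <- if (n > 0)
    sample(seq(config@nCodonsRange[1], config@nCodonsRange[2]), n,
           replace = TRUE) else integer(0)
  alignments <- vector("list", n)
  names(alignments) <- ids
  siteClassList <- vector("list", n)
  for (i in seq_len(n)) {
    om2 <- if (selected[i]) config@foregroundOmega2 else 1
    cls <- .branchSiteClasses(config@p0, config@p1, config@backgroundOmega,
                              om2)
    alignments[[i]] <- simulateCodonAlignment(
      config@tree, list(kappa = config@kappa, pi = pi, classes = cls),
      nCodons = lens[i], geneId = ids[i])
    siteClassList[[i]] <- attr(alignments[[i]], "siteClasses")
  }
  anno <- .simulateAnnotations(ids, selected, config)
  termOf <- split(anno$term_id, factor(anno$gene_id, levels = ids))
  truth <- data.frame(
    gene_id = ids, selected = selected,
    omega0 = rep(config@backgroundOmega, n),
    omega2 = ifelse(selected, config@foregroundOmega2, 1),
    n_codons = lens,
    terms = vapply(termOf, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(file.path(dir, "families"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n)) {
      writeCodonAlignment(alignments[[i]],
                          file.path(dir, "families", paste0(ids[i], ".fasta")))
    }
    utils::write.table(anno, file.path(dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(n_genes = n, n_selected = nSel, seed = config@seed,
                     tree = writeSpeciesTree(config@tree),
                     genes = ids)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- list(families = file.path(dir, "families"),
                  annotations = file.path(dir, "annotations.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  manifest = file.path(dir, "manifest.json"))
  }
  invisible(list(alignments = alignments, truth = truth, annotations = anno,
                 siteClasses = siteClassList, paths = paths))
}

.simulateAnnotations <- function(ids, selected, config) {
  n <- length(ids)
  if (n == 0L || config@nTerms == 0L)
    return(data.frame(gene_id = character(0), term_id = character(0)))
  terms <- sprintf("term_%03d", seq_len(config@nTerms))
  selIds <- ids[selected]
  rows <- list()
  for (j in seq_len(config@nTerms)) {
    size <- min(n, sample(seq(config@termSizeRange[1],
                              config@termSizeRange[2]), 1))
    if (j <= config@enrichedTerms && length(selIds) > 0) {
      nSel <- min(length(selIds), round(config@enrichmentBias * size))
      members <- c(sample(selIds, nSel),
                   sample(setdiff(ids, selIds), size - nSel))
    } else {
      members <- sample(ids, size)
    }
    rows[[j]] <- data.frame(gene_id = members, term_id = terms[j],
                            stringsAsFactors = FALSE)
  }
  anno <- do.call(rbind, rows)
  orphan <- setdiff(ids, anno$gene_id)
  if (length(orphan)) {
    anno <- rbind(anno, data.frame(
      gene_id = orphan,
      term_id = sample(terms, length(orphan), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  anno[order(anno$term_id, anno$gene_id), , drop = FALSE]
}

# Evolve one in-frame coding sequence by branch length 't' under the codon
# model (used for decoy construction).
.evolveCds <- function(cds, t, kappa, omega, pi) {
  idx <- codonStateIndex(substring(cds, seq(1, nchar(cds) - 2, 3),
                                   seq(3, nchar(cds), 3)))
  keep <- !is.na(idx)
  eig <- .codonEigen(kappa, omega, pi)
  P <- cpp_pmat(eig$lambda, eig$W1, eig$W2, t)
  out <- idx
  out[keep] <- .evolveStates(idx[keep], P)
  codons <- senseCodons()[out]
  codons[is.na(out)] <- "NNN"
  paste0(codons, collapse = "")
}

.randomDna <- function(n) {
  paste0(sample(.NUC, n, replace = TRUE), collapse = "")
}

#' Build a decoy transcript set for orthology testing
#'
#' From a set of reference CDS, emits (i) true-ortholog transcripts:
#' each CDS evolved by \code{orthologDivergence}, flanked by untranslated
#' random sequence and possibly truncated; (ii) paralog copies evolved by
#' the larger \code{paralogDivergence}; (iii) unrelated random sequences.
#' A manifest records the true label of every emitted transcript.
#'
#' @param cdsSet named \code{DNAStringSet} (or character vector) of
#'   in-frame CDS.
#' @param paralogDivergence extra branch length (expected substitutions
#'   per codon) for paralog copies.
#' @param fragmentation probability that an ortholog transcript is
#'   truncated; must lie in [0, 1].
#' @param seed integer seed.
#' @param orthologDivergence branch length separating transcript and CDS.
#' @param flankRange length range of the random UTR-like flanks.
#' @param nRandom number of unrelated random transcripts.
#' @param kappa,pi codon model parameters for the evolution steps.
#' @return list with \code{transcripts} (DNAStringSet) and \code{manifest}
#'   (data.frame transcript_id, source_cds, label).
#' @export
makeTranscriptDecoys <- function(cdsSet, paralogDivergence = 2,
                                 fragmentation = 0.3, seed = 1,
                                 orthologDivergence = 0.15,
                                 flankRange = c(30L, 90L), nRandom = 10L,
                                 kappa = 2.5, pi = equalCodonFrequencies()) {
  if (fragmentation > 1 || fragmentation < 0)
    stop("fragmentation must lie in [0, 1]")
  if (length(cdsSet) == 0L) stop("cdsSet must be non-empty")
  set.seed(seed)
  cds <- .namedChars(cdsSet)
  if (is.null(names(cds))) names(cds) <- sprintf("cds_%03d", seq_along(cds))
  out <- character(0)
  manifest <- list()
  for (nm in names(cds)) {
    core <- .evolveCds(cds[[nm]], orthologDivergence, kappa, 0.2, pi)
    if (stats::runif(1) < fragmentation) {
      keepFrac <- stats::runif(1, 0.5, 0.9)
      nKeep <- max(60L, floor(nchar(core) * keepFrac))
      startAt <- sample.int(max(1L, nchar(core) - nKeep + 1L), 1)
      core <- substr(core, startAt, min(nchar(core), startAt + nKeep - 1L))
    }
    flank5 <- .randomDna(sample(seq(flankRange[1], flankRange[2]), 1))
    flank3 <- .randomDna(sample(seq(flankRange[1], flankRange[2]), 1))
    tid <- paste0("tr_", nm)
    out[tid] <- paste0(flank5, core, flank3)
    manifest[[length(manifest) + 1L]] <-
      data.frame(transcript_id = tid, source_cds = nm, label = "ortholog",
                 stringsAsFactors = FALSE)
    pid <- paste0("par_", nm)
    out[pid] <- .evolveCds(cds[[nm]], paralogDivergence, kappa, 0.5, pi)
    manifest[[length(manifest) + 1L]] <-
      data.frame(transcript_id = pid, source_cds = nm, label = "paralog",
                 stringsAsFactors = FALSE)
  }
  for (r in seq_len(nRandom)) {
    rid <- sprintf("rand_%03d", r)
    out[rid] <- .randomDna(sample(300:900, 1))
    manifest[[length(manifest) + 1L]] <-
      data.frame(transcript_id = rid, source_cds = NA_character_,
                 label = "random", stringsAsFactors = FALSE)
  }
  list(transcripts = Biostrings::DNAStringSet(out),
       manifest = do.call(rbind, manifest))
}
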