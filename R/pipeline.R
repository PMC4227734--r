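#' Configuration for an end-to-end selection scan
#'
#' Bundles every stage threshold (with the study's standing defaults: PSG
#' alpha 0.05, saturation branch length 1.0, minimum trimmed length 200
#' bp, categories require more than 20 orthologs, ES cutoff 1.3) together
#' with the simulation settings and stage toggles.
#'
#' @param sim a \linkS4class{SimulationConfig} (its tree and seed drive
#'   the run) or \code{NULL} when loading inputs from \code{inputDir}.
#' @param outdir run directory (created).
#' @param inputDir directory holding \code{families/}, \code{annotations.tsv}
#'   (and optionally \code{truth.tsv}) when not simulating.
#' @param psgAlpha PSG significance level.
#' @param saturationThreshold third-position branch length at which a gene
#'   is called saturated.
#' @param minLenBp minimum trimmed alignment length in bp.
#' @param minCategoryOrthologs minimum member count for the category rate
#'   test (21 = strictly more than 20).
#' @param esThreshold enrichment-score cutoff.
#' @param trimMinBlock,trimMaxGapFraction block-trim settings.
#' @param lineages the two focal terminal lineages (A first = foreground).
#' @param pi codon frequency option for all fits.
#' @param stages named logical vector toggling \code{qc}, \code{trim}
#'   (the block-trim step inside QC; turn off for exact simulated
#'   alignments, where there are no unreliable regions to remove),
#'   \code{scan}, \code{rates}, \code{enrich}, \code{categoryScatter}.
#' @param seed run seed (defaults to the simulation seed).
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(sim = simulationConfig(), outdir = tempfile("run"),
                      inputDir = NULL, psgAlpha = 0.05,
                      saturationThreshold = 1.0, minLenBp = 200,
                      minCategoryOrthologs = 21, esThreshold = 1.3,
                      trimMinBlock = 5, trimMaxGapFraction = 0,
                      lineages = c("vlangalii", "przewalskii"),
                      pi = "f3x4",
                      stages = c(qc = TRUE, trim = TRUE, scan = TRUE,
                                 rates = TRUE, enrich = TRUE,
                                 categoryScatter = FALSE),
                      seed = NULL) {
  stopifnot(psgAlpha >= 0, saturationThreshold > 0, minLenBp > 0,
            minCategoryOrthologs > 0, esThreshold > 0)
  if (is.null(seed)) seed <- if (!is.null(sim)) sim@seed else 1L
  cfg <- list(sim = sim, outdir = outdir, inputDir = inputDir,
              psgAlpha = psgAlpha, saturationThreshold = saturationThreshold,
              minLenBp = minLenBp,
              minCategoryOrthologs = minCategoryOrthologs,
              esThreshold = esThreshold, trimMinBlock = trimMinBlock,
              trimMaxGapFraction = trimMaxGapFraction, lineages = lineages,
              pi = pi, stages = stages, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param file path to a JSON config file whose keys match the arguments
#'   of \code{runConfig} (simulation settings under \code{"sim"}).
#' @export
readRunConfig <- function(file) {
  js <- jsonlite::read_json(file, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(js$sim)) {
    simArgs <- js$sim
    if (!is.null(simArgs$tree))
      simArgs$tree <- readSpeciesTree(simArgs$tree)
    sim <- do.call(simulationConfig, simArgs)
  }
  args <- js[setdiff(names(js), "sim")]
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(runConfig, c(list(sim = sim), args))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end positive-selection scan
#'
#' Executes the enabled stages in order -- simulate (or load), QC
#' (block-trim, stop/length filter, saturation screen), branch-site scan,
#' free-ratio rates with the category binomial test, enrichment -- writing
#' every table as TSV and a machine-readable \code{summary.json} under the
#' run directory. Re-running with the same config and seed reproduces the
#' outputs. When a truth table is available the summary reports PSG recall
#' and precision against it.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @param verbose print stage progress.
#' @return invisible list: the summary plus the main per-stage tables.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)

  # --- inputs -------------------------------------------------------
  if (!is.null(config$sim)) {
    note("simulating %d gene families", config$sim@nGenes)
    study <- generateOrthologStudy(config$sim,
                                   dir = file.path(config$outdir, "sim"))
    tree <- config$sim@tree
  } else {
    if (is.null(config$inputDir)) stop("need either sim or inputDir")
    famDir <- file.path(config$inputDir, "families")
    if (!dir.exists(famDir)) stop("missing stage input: families/ directory")
    files <- list.files(famDir, pattern = "\\.fasta$", full.names = TRUE)
    alignments <- lapply(files, readCodonAlignment)
    names(alignments) <- vapply(alignments, geneId, "")
    annPath <- file.path(config$inputDir, "annotations.tsv")
    if (!file.exists(annPath)) stop("missing stage input: annotations.tsv")
    anno <- utils::read.delim(annPath, stringsAsFactors = FALSE)
    truPath <- file.path(config$inputDir, "truth.tsv")
    truth <- if (file.exists(truPath))
      utils::read.delim(truPath, stringsAsFactors = FALSE) else NULL
    study <- list(alignments = alignments, annotations = anno, truth = truth)
    treePath <- file.path(config$inputDir, "tree.nwk")
    tree <- if (file.exists(treePath)) readSpeciesTree(treePath)
            else defaultSpeciesTree()
  }
  counts <- c(simulated = length(study$alignments))
  summary <- list(seed = config$seed, lineages = config$lineages)

  # --- QC -----------------------------------------------------------
  alignments <- study$alignments
  if (isTRUE(config$stages[["qc"]])) {
    note("QC on %d genes", length(alignments))
    trimOff <- "trim" %in% names(config$stages) &&
      identical(unname(config$stages[["trim"]]), FALSE)
    trimmed <- if (trimOff) alignments
               else lapply(alignments, trimAlignmentBlocks,
                           minBlock = config$trimMinBlock,
                           maxGapFraction = config$trimMaxGapFraction)
    filt <- filterOrthologs(trimmed, minLengthBp = config$minLenBp)
    .writeTsv(filt$log, file.path(config$outdir, "qc_filter.tsv"))
    counts["after_filter"] <- length(filt$kept)
    sat <- saturationScreen(filt$kept, tree,
                            threshold = config$saturationThreshold)
    .writeTsv(sat, file.path(config$outdir, "saturation.tsv"))
    alignments <- filt$kept[!sat$saturated]
    counts["after_saturation"] <- length(alignments)
  }

  # --- branch-site scan ---------------------------------------------
  psgIds <- character(0)
  scanTab <- NULL
  if (isTRUE(config$stages[["scan"]])) {
    note("branch-site scan on %d genes", length(alignments))
    scanTab <- scanPositiveSelection(alignments, tree,
                                     alpha = config$psgAlpha,
                                     pi = config$pi, verbose = verbose)
    .writeTsv(scanTab, file.path(config$outdir, "branch_site_scan.tsv"))
    fits <- attr(scanTab, "fits")
    rec <- lapply(fits, function(f) list(
      gene_id = f@geneId, lnl_alt = f@lnLAlt, lnl_null = f@lnLNull,
      lrt = f@lrt, p_value = f@pValue, kappa = f@kappa, p0 = f@p0,
      p1 = f@p1, omega0 = f@omega0, omega2 = f@omega2))
    jsonlite::write_json(unname(rec),
                         file.path(config$outdir, "branch_site_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    psgIds <- scanTab$gene_id[scanTab$psg_flag]
    counts["scanned"] <- nrow(scanTab)
    counts["psgs"] <- length(psgIds)
  }

  # --- rates ---------------------------------------------------------
  rateTab <- NULL
  catTab <- NULL
  lineageSummary <- NULL
  if (isTRUE(config$stages[["rates"]]) && length(alignments) > 0) {
    note("free-ratio fits on %d genes", length(alignments))
    perGene <- lapply(alignments, function(a) {
      fit <- tryCatch(fitFreeRatio(a, tree, pi = config$pi, maxSweeps = 4),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      tb <- branchRates(fit)
      rA <- tb[tb$branch == config$lineages[1], ]
      rB <- tb[tb$branch == config$lineages[2], ]
      data.frame(gene_id = geneId(a), nA = rA$nhat, nB = rB$nhat,
                 kaks_A = rA$omega, kaks_B = rB$omega,
                 stringsAsFactors = FALSE)
    })
    rateTab <- do.call(rbind, Filter(Negate(is.null), perGene))
    .writeTsv(rateTab, file.path(config$outdir, "gene_rates.tsv"))
    lin <- concatenateAndFit(alignments, tree, config$lineages,
                             pi = config$pi)
    attr(lin, "fit") <- NULL
    lineageSummary <- lin
    jsonlite::write_json(
      lapply(seq_len(nrow(lin)), function(i) as.list(lin[i, ])),
      file.path(config$outdir, "lineage_rates.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    catTab <- categoryRateTest(study$annotations, rateTab,
                               lineages = config$lineages,
                               minGenes = config$minCategoryOrthologs)
    .writeTsv(catTab, file.path(config$outdir, "category_rates.tsv"))
    counts["categories_tested"] <- nrow(catTab)
    if (isTRUE(config$stages[["categoryScatter"]])) {
      sc <- categoryKaKsTable(alignments, study$annotations, tree,
                              lineages = config$lineages,
                              minGenes = config$minCategoryOrthologs,
                              pi = config$pi)
      .writeTsv(sc, file.path(config$outdir, "category_kaks.tsv"))
    }
  }

  # --- enrichment ----------------------------------------------------
  enrichTab <- NULL
  if (isTRUE(config$stages[["enrich"]]) && !is.null(scanTab)) {
    background <- scanTab$gene_id
    enrichTab <- fisherOverrepresentation(psgIds, background,
                                          study$annotations, mode = "ease")
    enrichTab <- classifyOverRepresented(enrichTab,
                                         esThreshold = config$esThreshold,
                                         pThreshold = config$psgAlpha)
    .writeTsv(enrichTab, file.path(config$outdir, "enrichment.tsv"))
    counts["terms_flagged"] <- sum(enrichTab$over_represented)
  }

  # --- report --------------------------------------------------------
  summary$counts <- as.list(counts)
  summary$psg_ids <- psgIds
  if (!is.null(study$truth) && !is.null(scanTab)) {
    truthSel <- study$truth$gene_id[study$truth$selected]
    analyzedSel <- intersect(truthSel, scanTab$gene_id)
    tp <- length(intersect(psgIds, truthSel))
    summary$psg_recall <- if (length(analyzedSel)) tp / length(analyzedSel)
                          else NA
    summary$psg_precision <- if (length(psgIds)) tp / length(psgIds) else NA
  }
  if (!is.null(catTab))
    summary$accelerated_categories <-
      as.list(table(catTab$accelerated_lineage[catTab$p_holm < 0.05]))
  if (!is.null(enrichTab))
    summary$over_represented_terms <-
      enrichTab$term_id[enrichTab$over_represented]
  if (!is.null(lineageSummary))
    summary$lineage_rates <- lapply(seq_len(nrow(lineageSummary)),
                                    function(i) as.list(lineageSummary[i, ]))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, scan = scanTab, rates = rateTab,
                 categories = catTab, enrichment = enrichTab,
                 lineages = lineageSummary, counts = counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concordance between assembly and Sanger-resequenced fragments
#'
#' Globally aligns each paired fragment with free end gaps, counts
#' mismatching aligned columns (internal gaps count as mismatches), and
#' reports per-fragment and total aligned lengths plus the percent
#' consistency \code{100 * (1 - mismatches / total length)}, rounded
#' half-up to 2 decimals. Unpaired fragments are listed as failed and
#' excluded from the totals.
#'
#' @param assembly,sanger named \code{DNAStringSet}s (or character
#'   vectors) of fragments.
#' @param pairing data.frame with columns \code{assembly}, \code{sanger};
#'   by default names shared between the two sets are paired.
#' @return list with \code{perFragment} (data.frame), \code{totalLength},
#'   \code{totalMismatches}, \code{percentConsistency}, \code{failed}.
#' @export
sangerConcordance <- function(assembly, sanger, pairing = NULL) {
  a <- .namedChars(assembly); s <- .namedChars(sanger)
  if (is.null(pairing)) {
    shared <- intersect(names(a), names(s))
    pairing <- data.frame(assembly = shared, sanger = shared,
                          stringsAsFactors = FALSE)
  }
  failed <- c(setdiff(names(a), pairing$assembly),
              setdiff(names(s), pairing$sanger))
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    x <- a[[pairing$assembly[i]]]; y <- s[[pairing$sanger[i]]]
    pa <- Biostrings::pairwiseAlignment(
      x, y, type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 5, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    len <- length(p)
    mism <- sum(p != q)
    data.frame(assembly = pairing$assembly[i], sanger = pairing$sanger[i],
               aligned_length = len, mismatches = mism,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  totLen <- sum(per$aligned_length)
  totMis <- sum(per$mismatches)
  pct <- floor(100 * (1 - totMis / totLen) * 100 + 0.5) / 100
  list(perFragment = per, totalLength = totLen, totalMismatches = totMis,
       percentConsistency = pct, failed = failed)
}

#' Percent consistency from printed totals
#'
#' The concordance arithmetic on already-tabulated totals: given a summed
#' aligned length and mismatch count, returns \code{100 * (1 -
#' mismatches/length)} rounded half-up to two decimals.
#'
#' @param totalLength total aligned length in bp.
#' @param mismatches total differing sites.
#' @return percent consistency (scalar).
#' @examples
#' percentConsistency(2799, 12)  # 99.57
#' percentConsistency(4485, 3)   # 99.93
#' @export
percentConsistency <- function(totalLength, mismatches) {
  stopifnot(totalLength > 0, mismatches >= 0, mismatches <= totalLength)
  floor(100 * (1 - mismatches / totalLength) * 100 + 0.5) / 100
}
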