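#' Pipeline configuration
#'
#' Collects every path and tunable of an end-to-end run. Threshold defaults
#' are the published calling rules: locus q < 0.05 with |delta beta| > 0.1,
#' probe fold change > 2 with uncorrected p < 0.05, promoter window
#' -2500/+500 bp, pathway q < 0.05, and 10,000 permutation rounds.
#'
#' @param inputDir Directory holding a bundle as written by
#'   [simulateBundle()] (individual paths may be overridden).
#' @param outputDir Directory for stage outputs and the run report.
#' @param beta,manifest,tss,expression,probeMap,catalog,supplement,gmt
#'   Individual input paths (default: the bundle layout under `inputDir`).
#' @param comparisons List of length-2 group comparisons (first group
#'   versus second), run for both omics and combined by union.
#' @param dmlQ,dmlDelta,degFold,degP,enrichQ Calling thresholds.
#' @param upstream,downstream Promoter window extent.
#' @param traitPatterns GWAS trait patterns.
#' @param nPermutations,seed Permutation test settings.
#' @param enrichBackground `"universe"` (annotation universe: union of the
#'   three assay backgrounds) for the enrichment `N`.
#' @return A validated configuration list of class `megraConfig`.
#' @export
pipelineConfig <- function(inputDir, outputDir = file.path(inputDir, "out"),
                           beta = file.path(inputDir, "beta_matrix.tsv"),
                           manifest = file.path(inputDir, "locus_manifest.bed"),
                           tss = file.path(inputDir, "tss_table.tsv"),
                           expression = file.path(inputDir, "expression_matrix.tsv"),
                           probeMap = file.path(inputDir, "probe_map.tsv"),
                           catalog = file.path(inputDir, "gwas_catalog.tsv"),
                           supplement = file.path(inputDir, "gwas_supplement.txt"),
                           gmt = file.path(inputDir, "pathways.gmt"),
                           comparisons = list(c("RA", "OA"), c("RA", "NL")),
                           dmlQ = 0.05, dmlDelta = 0.1,
                           degFold = 2, degP = 0.05, enrichQ = 0.05,
                           upstream = 2500L, downstream = 500L,
                           traitPatterns = "rheumatoid arthritis",
                           nPermutations = 10000L, seed = 1L,
                           enrichBackground = "universe") {
  stopifnot(dmlQ > 0, dmlDelta > 0, degFold > 0, degP > 0, enrichQ > 0,
            upstream + downstream > 0, nPermutations >= 1)
  structure(list(inputDir = inputDir, outputDir = outputDir, beta = beta,
                 manifest = manifest, tss = tss, expression = expression,
                 probeMap = probeMap, catalog = catalog,
                 supplement = supplement, gmt = gmt,
                 comparisons = comparisons, dmlQ = dmlQ, dmlDelta = dmlDelta,
                 degFold = degFold, degP = degP, enrichQ = enrichQ,
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 traitPatterns = traitPatterns,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed),
                 enrichBackground = enrichBackground),
            class = "megraConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full integration pipeline
#'
#' Executes every stage against a bundle of input files: DMG calling
#' (per-locus Welch tests, promoter-window mapping, union over
#' comparisons), DEG calling (per-probe tests, any-probe rule, union),
#' GWAS gene extraction, evidence-ledger construction, the three-way
#' overlap permutation test against the assay-identifiable backgrounds,
#' and MEG pathway enrichment. Writes stage tables and a JSON run report
#' under `config$outputDir` and returns the report. Fully deterministic
#' under a fixed `config$seed`.
#'
#' @param config A configuration from [pipelineConfig()].
#' @param verbose Log per-stage input/output counts.
#' @return A report list: set sizes, Venn counts, triple-evidence genes,
#'   MEG count, permutation result and significant pathways.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (!dir.exists(config$outputDir))
    dir.create(config$outputDir, recursive = TRUE)

  beta <- .stage("read", readBetaMatrix(config$beta))
  manifest <- .stage("read", readLocusManifest(config$manifest))
  tss <- .stage("read", readTssTable(config$tss))
  expr <- .stage("read", readExpressionMatrix(config$expression))
  probeMap <- .stage("read", readProbeMap(config$probeMap))
  catalog <- .stage("read", readGwasCatalog(config$catalog))
  supplement <- .stage("read", readGeneList(config$supplement))
  pathways <- .stage("read", readGmt(config$gmt))
  say("inputs: ", nrow(beta), " loci, ", nrow(expr), " probes, ",
      nrow(catalog), " catalog rows, ", length(pathways), " pathways")

  methGroups <- groupsFromSampleIds(colnames(beta))
  exprGroups <- groupsFromSampleIds(colnames(expr))

  dmgRes <- .stage("dmg",
    callDmg(beta, methGroups, manifest, tss, config$comparisons,
            config$dmlQ, config$dmlDelta, config$upstream, config$downstream))
  say("dmg: ", length(dmgRes$combined), " combined DMGs")

  degRes <- .stage("deg",
    callDeg(expr, probeMap, exprGroups, config$comparisons,
            config$degFold, config$degP))
  say("deg: ", length(degRes$combined), " combined DEGs")

  gwasGenes <- .stage("gwas",
    extractTraitGenes(catalog, config$traitPatterns, supplement))
  say("gwas: ", length(gwasGenes), " trait genes")

  ledger <- .stage("integrate",
    buildLedger(dmgRes$combined, degRes$combined, gwasGenes))
  meg <- megSet(ledger, 2L)
  triple <- megSet(ledger, 3L)
  say("integrate: ", length(meg), " MEGs, ", length(triple),
      " triple-evidence genes")

  windows <- buildPromoterWindows(tss, config$upstream, config$downstream)
  backgrounds <- list(
    methylationBackground(manifest, windows,
                          max(1L, length(dmgRes$combined))),
    expressionBackground(probeMap, max(1L, length(degRes$combined))),
    gwasBackground(catalog, max(1L, length(gwasGenes))))
  perm <- .stage("permute",
    permuteOverlap(backgrounds, observed = length(triple),
                   nPermutations = config$nPermutations,
                   seed = config$seed))
  say("permute: p = ", format(pValue(perm), digits = 4))

  universe <- sort(unique(c(backgroundGenes(backgrounds[[1]]),
                            backgroundGenes(backgrounds[[2]]),
                            backgroundGenes(backgrounds[[3]]))))
  enr <- .stage("enrich", enrichPathways(meg, pathways, universe))
  sig <- filterSignificant(enr, config$enrichQ)
  say("enrich: ", nrow(sig), " significant pathway(s) at q < ",
      config$enrichQ)

  o <- function(f) file.path(config$outputDir, f)
  for (nm in names(dmgRes$dml))
    utils::write.table(dmgRes$dml[[nm]], o(sprintf("dml_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dmgRes$combined, o("dmg_genes.txt"))
  writeLines(degRes$combined, o("deg_genes.txt"))
  writeLines(gwasGenes, o("gwas_genes.txt"))
  writeLedger(ledger, o("evidence_ledger.tsv"))
  utils::write.table(enr, o("enrichment.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sig, o("enrichment_significant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- list(
    n_dmg = length(dmgRes$combined),
    n_deg = length(degRes$combined),
    n_gwas = length(gwasGenes),
    n_meg = length(meg),
    venn = as.list(vennCounts(ledger)),
    triple_evidence = triple,
    background_sizes = vapply(backgrounds, function(b)
      length(backgroundGenes(b)), integer(1)),
    permutation = list(observed = observedOverlap(perm),
                       n = perm@nPermutations,
                       p_value = pValue(perm),
                       seed = perm@seed,
                       null_counts = as.list(nullCounts(perm))),
    significant_pathways = sig$pathway,
    enrichment_top = utils::head(enr, 10))
  jsonlite::write_json(report, o("run_report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(report, list(ledger = ledger, permutationResult = perm,
                           enrichment = enr)))
}
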