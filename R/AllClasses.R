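#' @import methods
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics bundle. Defaults reproduce the
#' structure of the study design the pipeline targets: 11 RA / 11 OA / 6
#' normal (NL) methylation arrays, 9 RA / 11 OA / 11 NL expression arrays, a
#' 17,450-gene universe, 114 RA GWAS genes, and seven genes planted with all
#' three forms of evidence. Construct with [simulationConfig()].
#'
#' @slot seed Integer seed driving every random draw.
#' @slot nGenes Size of the gene universe.
#' @slot groupsMeth,groupsExpr Named integer vectors of per-group array
#'   counts for the methylation and expression experiments.
#' @slot lociPerPromoter,probesPerGene,tssPerGene Integer ranges
#'   (length-2 vectors) for per-gene feature counts.
#' @slot nMethCallable,nExprCallable,nCatalogReported Sizes of the three
#'   identifiable-gene backgrounds (genes with promoter loci on the
#'   methylation array, genes with expression probes, genes reported in the
#'   GWAS catalog).
#' @slot nPlantedDmg,nPlantedDeg Number of genes planted with a methylation
#'   or expression effect (each includes the triple-evidence genes).
#' @slot deltaBeta Planted promoter methylation difference (beta scale,
#'   RA minus the other groups).
#' @slot foldChangeDeg Planted linear-scale expression fold change.
#' @slot plantedTriple Gene symbols planted with all three evidence types.
#' @slot gwasTraitGenes Total size of the RA GWAS gene set (catalog plus
#'   supplementary list).
#' @slot betaNoiseSd Beta-scale noise standard deviation.
#' @slot exprCv Coefficient of variation of expression intensities.
#' @slot plantedPathwaySize,plantedPathwayMegCount Size of the planted
#'   enriched pathway and the number of planted triple-evidence genes it
#'   contains.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nGenes = "integer",
    groupsMeth = "integer",
    groupsExpr = "integer",
    lociPerPromoter = "integer",
    probesPerGene = "integer",
    tssPerGene = "integer",
    nMethCallable = "integer",
    nExprCallable = "integer",
    nCatalogReported = "integer",
    nPlantedDmg = "integer",
    nPlantedDeg = "integer",
    deltaBeta = "numeric",
    foldChangeDeg = "numeric",
    plantedTriple = "character",
    gwasTraitGenes = "integer",
    betaNoiseSd = "numeric",
    exprCv = "numeric",
    plantedPathwaySize = "integer",
    plantedPathwayMegCount = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@groupsMeth < 2L) || any(object@groupsExpr < 2L))
    msg <- c(msg, "all group counts must be >= 2")
  if (object@deltaBeta < 0) msg <- c(msg, "deltaBeta must be >= 0")
  if (object@foldChangeDeg < 1) msg <- c(msg, "foldChangeDeg must be >= 1")
  if (length(object@plantedTriple) > object@nPlantedDmg ||
      length(object@plantedTriple) > object@nPlantedDeg ||
      length(object@plantedTriple) > object@gwasTraitGenes)
    msg <- c(msg, "planted triple genes must fit inside every planted set")
  if (object@nMethCallable > object@nGenes ||
      object@nExprCallable > object@nGenes ||
      object@nCatalogReported > object@nGenes)
    msg <- c(msg, "background sizes cannot exceed the gene universe")
  for (nm in c("lociPerPromoter", "probesPerGene", "tssPerGene")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
      msg <- c(msg, sprintf("%s must be an increasing range of positive integers", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene evidence ledger
#'
#' Boolean evidence flags (differential methylation, differential expression,
#' GWAS report) and the evidence count for every gene carried by at least one
#' evidence stream. Construct with [buildLedger()]; query with [megSet()],
#' [vennCounts()] and [evidenceTable()].
#'
#' @slot table A data.frame with columns `gene`, `in_dmg`, `in_deg`,
#'   `in_gwas`, `evidence_count`, sorted lexicographically by gene.
#' @exportClass EvidenceLedger
setClass("EvidenceLedger", representation(table = "data.frame"))

setValidity("EvidenceLedger", function(object) {
  tb <- object@table
  need <- c("gene", "in_dmg", "in_deg", "in_gwas", "evidence_count")
  if (!all(need %in% names(tb)))
    return("ledger table must have columns gene, in_dmg, in_deg, in_gwas, evidence_count")
  if (anyDuplicated(tb$gene)) return("duplicate genes in ledger")
  counts <- tb$in_dmg + tb$in_deg + tb$in_gwas
  if (nrow(tb) && !all(counts == tb$evidence_count))
    return("evidence_count must equal the number of TRUE flags")
  if (nrow(tb) && any(counts == 0L))
    return("ledger must only contain genes with at least one evidence flag")
  if (is.unsorted(tb$gene)) return("ledger must be sorted by gene")
  TRUE
})

#' Identifiable-gene background for one assay
#'
#' The set of genes an assay could in principle have flagged, together with
#' the number of genes the assay actually flagged (the permutation draw
#' size). Construct with [assayBackground()], or from data with
#' [methylationBackground()], [expressionBackground()] and
#' [gwasBackground()].
#'
#' @slot label One of `"methylation"`, `"expression"`, `"gwas"` (free text
#'   allowed).
#' @slot genes Character vector of identifiable gene symbols (unique).
#' @slot drawSize Number of genes resampled from `genes` per permutation
#'   round.
#' @exportClass AssayBackground
setClass("AssayBackground",
  representation(label = "character", genes = "character",
                 drawSize = "integer"))

setValidity("AssayBackground", function(object) {
  if (anyDuplicated(object@genes)) return("background genes must be unique")
  if (length(object@drawSize) != 1L || object@drawSize < 1L)
    return("drawSize must be a single positive integer")
  if (object@drawSize > length(object@genes))
    return("drawSize cannot exceed the background size")
  TRUE
})

#' Result of the gene-set overlap permutation test
#'
#' Null distribution of the k-way overlap obtained by resampling
#' evidence-set-sized gene draws from the assay backgrounds, with the
#' empirical p-value `(b + 1) / (n + 1)` where `b` counts null rounds whose
#' overlap reaches the observed value.
#'
#' @slot observed Observed overlap size.
#' @slot nPermutations Number of permutation rounds.
#' @slot nullCounts Named integer vector: histogram of null overlap sizes
#'   (names are overlap sizes).
#' @slot pValue Empirical p-value.
#' @slot seed Seed used for the resampling.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(observed = "integer", nPermutations = "integer",
                 nullCounts = "integer", pValue = "numeric",
                 seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (sum(object@nullCounts) != object@nPermutations)
    return("null histogram must sum to the number of permutations")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})
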