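#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class] object. The defaults encode
#' the study design the pipeline targets: a 17,450-gene universe, 11/11/6
#' RA/OA/NL methylation arrays, 9/11/11 RA/OA/NL expression arrays, 114 RA
#' GWAS genes, seven genes planted with all three evidence types, a planted
#' promoter methylation difference of 0.25 beta units and a planted 3-fold
#' expression change, both applied to the RA group against OA and NL.
#'
#' @param seed Integer seed.
#' @param nGenes Gene universe size.
#' @param groupsMeth,groupsExpr Named per-group array counts.
#' @param lociPerPromoter,probesPerGene,tssPerGene Length-2 integer ranges.
#' @param nMethCallable,nExprCallable,nCatalogReported Identifiable
#'   background sizes for the three assays.
#' @param nPlantedDmg,nPlantedDeg Planted effect-set sizes (include the
#'   triple-evidence genes).
#' @param deltaBeta Planted beta difference (RA minus others).
#' @param foldChangeDeg Planted linear fold change (RA over others).
#' @param plantedTriple Symbols planted into all three evidence streams.
#' @param gwasTraitGenes Total RA GWAS gene-set size.
#' @param betaNoiseSd Beta-scale noise standard deviation.
#' @param exprCv Coefficient of variation of intensities.
#' @param plantedPathwaySize,plantedPathwayMegCount Planted enriched pathway
#'   size and the number of planted triple genes inside it.
#' @return A `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 500, nMethCallable = 480,
#'                         nExprCallable = 460, nCatalogReported = 300)
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 17450L,
                             groupsMeth = c(RA = 11L, OA = 11L, NL = 6L),
                             groupsExpr = c(RA = 9L, OA = 11L, NL = 11L),
                             lociPerPromoter = c(1L, 6L),
                             probesPerGene = c(1L, 3L),
                             tssPerGene = c(1L, 4L),
                             nMethCallable = 17000L,
                             nExprCallable = 16000L,
                             nCatalogReported = 10000L,
                             nPlantedDmg = 60L,
                             nPlantedDeg = 60L,
                             deltaBeta = 0.25,
                             foldChangeDeg = 3.0,
                             plantedTriple = c("AIRE", "CASP8", "CSF2",
                                               "ELMO1", "ETS1", "HLA-DQA1",
                                               "LBH"),
                             gwasTraitGenes = 114L,
                             betaNoiseSd = 0.05,
                             exprCv = 0.2,
                             plantedPathwaySize = 89L,
                             plantedPathwayMegCount = 7L) {
  new("SimulationConfig",
      seed = as.integer(seed), nGenes = as.integer(nGenes),
      groupsMeth = stats::setNames(as.integer(groupsMeth), names(groupsMeth)),
      groupsExpr = stats::setNames(as.integer(groupsExpr), names(groupsExpr)),
      lociPerPromoter = as.integer(lociPerPromoter),
      probesPerGene = as.integer(probesPerGene),
      tssPerGene = as.integer(tssPerGene),
      nMethCallable = as.integer(nMethCallable),
      nExprCallable = as.integer(nExprCallable),
      nCatalogReported = as.integer(nCatalogReported),
      nPlantedDmg = as.integer(nPlantedDmg),
      nPlantedDeg = as.integer(nPlantedDeg),
      deltaBeta = as.numeric(deltaBeta),
      foldChangeDeg = as.numeric(foldChangeDeg),
      plantedTriple = normalizeSymbols(plantedTriple),
      gwasTraitGenes = as.integer(gwasTraitGenes),
      betaNoiseSd = as.numeric(betaNoiseSd),
      exprCv = as.numeric(exprCv),
      plantedPathwaySize = as.integer(plantedPathwaySize),
      plantedPathwayMegCount = as.integer(plantedPathwayMegCount))
}

# Deterministic shared scaffold: gene universe, genomic layout, TSS models,
# planted evidence sets and identifiable backgrounds. Every simulate* call
# rebuilds it from config@seed so the pieces of a bundle are consistent.
.simUniverse <- function(config) {
  set.seed(config@seed)
  nG <- config@nGenes
  triple <- config@plantedTriple
  nT <- length(triple)
  genes <- sprintf("GENE%05d", seq_len(nG))
  if (nT > 0) genes[seq_len(nT)] <- triple

  # non-overlapping genomic layout: one gene per 100 kb slot so promoter
  # windows of different genes can never overlap (TSS offsets stay < 30 kb)
  chroms <- paste0("chr", ((seq_len(nG) - 1L) %% 22L) + 1L)
  slot <- (seq_len(nG) - 1L) %/% 22L
  tss0 <- 100000L + 100000L * slot
  strand <- sample(c("+", "-"), nG, replace = TRUE)

  nTss <- sample(seq(config@tssPerGene[1], config@tssPerGene[2]),
                 nG, replace = TRUE)
  gi <- rep.int(seq_len(nG), nTss)
  extra <- which(sequence(nTss) > 1L)
  offs <- integer(length(gi))
  offs[extra] <- sample(1000:27000, length(extra), replace = TRUE)
  tssTable <- data.frame(
    gene = genes[gi],
    chrom = chroms[gi],
    strand = strand[gi],
    tss_position = tss0[gi] + offs,
    transcript_label = paste0("v", sequence(nTss)),
    stringsAsFactors = FALSE)

  pool <- genes[-seq_len(nT)]
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  nSharedDD <- max(0L, round(0.35 * (min(config@nPlantedDmg, config@nPlantedDeg) - nT)))
  nDmgGwas <- max(0L, round(0.25 * (config@nPlantedDmg - nT - nSharedDD)))
  nDegGwas <- max(0L, round(0.25 * (config@nPlantedDeg - nT - nSharedDD)))
  sharedDD <- take(nSharedDD)
  dmgGwas <- take(nDmgGwas)
  degGwas <- take(nDegGwas)
  dmgOnly <- take(max(0L, config@nPlantedDmg - nT - nSharedDD - nDmgGwas))
  degOnly <- take(max(0L, config@nPlantedDeg - nT - nSharedDD - nDegGwas))
  plantedDmg <- c(triple, sharedDD, dmgGwas, dmgOnly)
  plantedDeg <- c(triple, sharedDD, degGwas, degOnly)

  nFill <- max(0L, config@gwasTraitGenes - nT - nDmgGwas - nDegGwas)
  gwasFill <- take(nFill)
  gwasSet <- c(triple, dmgGwas, degGwas, gwasFill)
  # supplementary meta-analysis list: a tail of genes only on that list,
  # plus a few catalog duplicates exercising set-union semantics
  nSuppOnly <- min(20L, length(gwasFill))
  suppOnly <- if (nSuppOnly > 0) gwasFill[seq(length(gwasFill) - nSuppOnly + 1L, length(gwasFill))] else character()
  catalogRa <- setdiff(gwasSet, suppOnly)
  supplement <- c(suppOnly, catalogRa[seq_len(min(4L, length(catalogRa)))])

  fillBackground <- function(mustHave, n) {
    rest <- setdiff(genes, mustHave)
    need <- n - length(mustHave)
    if (need < 0) stop("background smaller than its mandatory members")
    c(mustHave, sample(rest, need))
  }
  methCallable <- fillBackground(plantedDmg, config@nMethCallable)
  exprCallable <- fillBackground(plantedDeg, config@nExprCallable)
  catalogReported <- fillBackground(catalogRa, config@nCatalogReported)

  list(genes = genes, chroms = chroms, tss0 = tss0, strand = strand,
       tssTable = tssTable, nTss = nTss,
       tssRowStart = c(0L, cumsum(nTss))[seq_len(nG)] + 1L,
       plantedDmg = plantedDmg, plantedDeg = plantedDeg,
       gwasSet = gwasSet, catalogRa = catalogRa, supplement = supplement,
       methCallable = methCallable, exprCallable = exprCallable,
       catalogReported = catalogReported)
}

.sampleIds <- function(groups) {
  unlist(lapply(names(groups), function(g)
    sprintf("%s_%02d", g, seq_len(groups[[g]]))), use.names = FALSE)
}

#' Simulate a promoter methylation experiment
#'
#' Generates a beta-value matrix, a BED-like locus manifest and a TSS table.
#' Every methylation-callable gene receives 1-6 CpG loci placed inside a
#' promoter window (-2500/+500 bp of one of its TSSs, in transcription
#' direction); a random 10% of genes additionally receive a distal locus 40
#' kb downstream of the primary TSS, outside every window. Genes planted as
#' differentially methylated get an RA-group beta shift of `deltaBeta` at
#' their first promoter locus. Noise is drawn on the logit scale (scaled so
#' the beta-scale standard deviation is about `betaNoiseSd`) and values are
#' clipped to \[0.01, 0.99\], mimicking array beta distributions.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with `beta` (loci x samples matrix), `groups` (factor per
#'   sample), `manifest` (data.frame `chrom`, `start`, `end`, `locus_id`;
#'   0-based half-open) and `tss` (data.frame `gene`, `chrom`, `strand`,
#'   `tss_position`, `transcript_label`).
#' @export
simulateMethylation <- function(config) {
  u <- .simUniverse(config)
  set.seed(config@seed + 1L)
  callable <- u$methCallable
  idx <- match(callable, u$genes)

  nl <- sample(seq(config@lociPerPromoter[1], config@lociPerPromoter[2]),
               length(callable), replace = TRUE)
  gi <- rep.int(seq_along(callable), nl)
  # choose one TSS of the gene per locus, uniformly (tssTable rows are
  # grouped by universe gene index, so offsets index directly)
  ug <- idx[gi]
  pick <- floor(stats::runif(length(ug)) * u$nTss[ug])
  pickTss <- u$tssTable$tss_position[u$tssRowStart[ug] + pick]
  strandLoc <- u$strand[idx][gi]
  off <- sample(0:2999, length(gi), replace = TRUE)
  start0 <- ifelse(strandLoc == "+", pickTss - 2500L, pickTss - 500L) + off

  # distal loci beyond every promoter window of their gene
  distGene <- which(stats::runif(length(callable)) < 0.10)
  distStart <- u$tss0[idx][distGene] + 40000L

  chrom <- c(u$chroms[idx][gi], u$chroms[idx][distGene])
  start0 <- c(start0, distStart)
  nLoci <- length(start0)
  manifest <- data.frame(chrom = chrom,
                         start = as.integer(start0),
                         end = as.integer(start0 + 2L),
                         locus_id = sprintf("cg%08d", seq_len(nLoci)),
                         stringsAsFactors = FALSE)

  samples <- .sampleIds(config@groupsMeth)
  groupOf <- factor(sub("_.*$", "", samples), levels = names(config@groupsMeth))

  mu <- stats::runif(nLoci, 0.15, 0.80)
  plantedLocus <- rep(FALSE, nLoci)
  firstLocusOfGene <- c(match(seq_along(callable), gi), integer(0))
  isPlantedGene <- u$genes[idx] %in% u$plantedDmg
  pl <- firstLocusOfGene[which(isPlantedGene)]
  plantedLocus[pl] <- TRUE
  mu[pl] <- stats::runif(length(pl), 0.20, 0.55)

  muMat <- matrix(mu, nLoci, length(samples))
  raCols <- which(groupOf == "RA")
  muMat[plantedLocus, raCols] <- muMat[plantedLocus, raCols] + config@deltaBeta

  sdLogit <- config@betaNoiseSd / (muMat * (1 - muMat))
  beta <- stats::plogis(stats::qlogis(muMat) +
                        matrix(stats::rnorm(length(muMat)), nLoci) * sdLogit)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(manifest$locus_id, samples)

  list(beta = beta, groups = stats::setNames(groupOf, samples),
       manifest = manifest, tss = u$tssTable)
}

#' Simulate a probe-level expression experiment
#'
#' Generates positive intensities with log-normal noise at the configured
#' coefficient of variation. Every expression-callable gene receives 1-3
#' probes; genes planted as differentially expressed carry the configured
#' fold change on their first probe only, so multi-probe planted genes
#' exercise the any-probe gene-calling rule. Twenty unmapped probes (empty
#' gene field) are appended.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with `intensity` (probes x samples matrix), `groups`
#'   (factor per sample) and `probeMap` (data.frame `probe_id`, `gene`).
#' @export
simulateExpression <- function(config) {
  u <- .simUniverse(config)
  set.seed(config@seed + 2L)
  callable <- u$exprCallable

  np <- sample(seq(config@probesPerGene[1], config@probesPerGene[2]),
               length(callable), replace = TRUE)
  gi <- rep.int(seq_along(callable), np)
  geneOfProbe <- callable[gi]
  nUnmapped <- 20L
  geneOfProbe <- c(geneOfProbe, rep("", nUnmapped))
  nProbes <- length(geneOfProbe)
  probeIds <- sprintf("A_23_P%06d", seq_len(nProbes))

  samples <- .sampleIds(config@groupsExpr)
  groupOf <- factor(sub("_.*$", "", samples), levels = names(config@groupsExpr))

  base <- exp(stats::runif(nProbes, log(30), log(3000)))
  firstProbeOfGene <- match(seq_along(callable), gi)
  plantedProbe <- rep(FALSE, nProbes)
  plantedProbe[firstProbeOfGene[callable %in% u$plantedDeg]] <- TRUE

  muMat <- matrix(base, nProbes, length(samples))
  raCols <- which(groupOf == "RA")
  muMat[plantedProbe, raCols] <- muMat[plantedProbe, raCols] * config@foldChangeDeg

  sigma <- sqrt(log(1 + config@exprCv^2))
  intensity <- muMat * exp(matrix(stats::rnorm(length(muMat), 0, sigma), nProbes))
  dimnames(intensity) <- list(probeIds, samples)

  list(intensity = intensity,
       groups = stats::setNames(groupOf, samples),
       probeMap = data.frame(probe_id = probeIds, gene = geneOfProbe,
                             stringsAsFactors = FALSE))
}

#' Simulate a GWAS-catalog-style association table
#'
#' Emulates a published-GWAS catalog: rows carry a trait, SNP identifiers, an
#' association p-value and a reported-gene cell. RA rows (several trait
#' spellings) jointly report the catalog part of the RA gene set; decoy rows
#' for other traits report the remainder of the catalog-reported background.
#' Multi-gene cells ("GENE1, GENE2"), placeholder cells ("NR", "intergenic",
#' "-") and a supplementary one-symbol-per-line meta-analysis list (with a
#' few genes duplicating catalog entries) are all included, so the union of
#' catalog RA genes and supplement has exactly `gwasTraitGenes` members.
#'
#' @param config A [SimulationConfig-class].
#' @return A list with `catalog` (data.frame with columns `DISEASE/TRAIT`,
#'   `SNPS`, `P-VALUE`, `REPORTED GENE(S)`) and `supplement` (character).
#' @export
simulateGwasCatalog <- function(config) {
  u <- .simUniverse(config)
  set.seed(config@seed + 3L)

  packRows <- function(genes, traits) {
    # pack genes into cells of size 1 (70%), 2 (20%) or 3 (10%)
    cells <- character(0)
    i <- 1L
    while (i <= length(genes)) {
      sz <- sample(c(1L, 2L, 3L), 1L, prob = c(0.7, 0.2, 0.1))
      sz <- min(sz, length(genes) - i + 1L)
      cells <- c(cells, paste(genes[i:(i + sz - 1L)], collapse = ", "))
      i <- i + sz
    }
    data.frame(
      `DISEASE/TRAIT` = sample(traits, length(cells), replace = TRUE),
      SNPS = sprintf("rs%d", sample.int(99999999L, length(cells))),
      `P-VALUE` = sprintf("%.0fE-%02d", sample(1:9, length(cells), TRUE),
                          sample(6:40, length(cells), TRUE)),
      `REPORTED GENE(S)` = cells,
      check.names = FALSE, stringsAsFactors = FALSE)
  }

  raTraits <- c("Rheumatoid arthritis",
                "Rheumatoid arthritis (ACPA-positive)",
                "Rheumatoid arthritis severity")
  decoyTraits <- c("Type 2 diabetes", "Crohn's disease", "Height",
                   "Systemic lupus erythematosus", "Coronary artery disease",
                   "Body mass index", "Asthma", "Ulcerative colitis")
  raRows <- packRows(sample(u$catalogRa), raTraits)
  decoyGenes <- sample(setdiff(u$catalogReported, u$catalogRa))
  decoyRows <- packRows(decoyGenes, decoyTraits)
  placeholder <- data.frame(
    `DISEASE/TRAIT` = c("Rheumatoid arthritis", "Rheumatoid arthritis",
                        "Height", "Asthma"),
    SNPS = sprintf("rs%d", sample.int(99999999L, 4L)),
    `P-VALUE` = c("5E-08", "2E-09", "1E-12", "3E-07"),
    `REPORTED GENE(S)` = c("NR", "intergenic", "-", ""),
    check.names = FALSE, stringsAsFactors = FALSE)

  catalog <- rbind(raRows, decoyRows, placeholder)
  catalog <- catalog[sample.int(nrow(catalog)), , drop = FALSE]
  rownames(catalog) <- NULL
  list(catalog = catalog, supplement = u$supplement)
}

#' Simulate a KEGG-style pathway collection
#'
#' Generates a GMT-ready named list of gene sets: one planted pathway of
#' `plantedPathwaySize` members containing `plantedPathwayMegCount` of the
#' planted triple-evidence genes (its remaining members avoid every other
#' planted evidence gene, so its overlap with recovered MEGs is controlled),
#' plus 24 decoy pathways with sizes spanning 30-300 drawn from the rest of
#' the universe.
#'
#' @param config A [SimulationConfig-class].
#' @return A named list of character vectors; `attr(, "description")` holds
#'   the GMT description column, and `attr(, "planted")` names the planted
#'   pathway.
#' @export
simulatePathways <- function(config) {
  u <- .simUniverse(config)
  set.seed(config@seed + 4L)
  plantedEvidence <- unique(c(u$plantedDmg, u$plantedDeg, u$gwasSet))
  nonEvidence <- setdiff(u$genes, plantedEvidence)

  nMeg <- min(config@plantedPathwayMegCount, length(config@plantedTriple))
  planted <- c(config@plantedTriple[seq_len(nMeg)],
               sample(nonEvidence, config@plantedPathwaySize - nMeg))
  pw <- list(hsa05323_Rheumatoid_arthritis = planted)
  for (i in seq_len(24L)) {
    sz <- sample(30:300, 1L)
    pw[[sprintf("hsa%05d_Decoy_pathway_%02d", 10000L + i, i)]] <-
      sample(nonEvidence, sz)
  }
  attr(pw, "description") <- stats::setNames(
    c("planted enriched pathway", rep("decoy pathway", 24L)), names(pw))
  attr(pw, "planted") <- names(pw)[1L]
  pw
}

#' Write a complete synthetic bundle to disk
#'
#' Runs all four generators and serialises every pipeline input in its
#' on-disk dialect, together with a truth ledger (JSON) recording which
#' genes were planted with which evidence and which pathway was planted
#' enriched. Outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of file paths plus the `truth` list.
#' @export
simulateBundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  u <- .simUniverse(config)
  meth <- simulateMethylation(config)
  expr <- simulateExpression(config)
  gwas <- simulateGwasCatalog(config)
  pw <- simulatePathways(config)

  p <- function(f) file.path(dir, f)
  writeMatrixTsv(meth$beta, p("beta_matrix.tsv"), idColumn = "locus_id")
  utils::write.table(meth$manifest, p("locus_manifest.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(meth$tss, p("tss_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeMatrixTsv(expr$intensity, p("expression_matrix.tsv"),
                 idColumn = "probe_id")
  utils::write.table(expr$probeMap, p("probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gwas$catalog, p("gwas_catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(gwas$supplement, p("gwas_supplement.txt"))
  writeGmt(pw, p("pathways.gmt"))

  truth <- list(universe = u$genes,
                planted_dmg = u$plantedDmg,
                planted_deg = u$plantedDeg,
                gwas_genes = sort(unique(c(u$catalogRa, u$supplement))),
                planted_triple = config@plantedTriple,
                planted_pathway = attr(pw, "planted"),
                meth_callable = sort(u$methCallable),
                expr_callable = sort(u$exprCallable),
                catalog_reported = sort(u$catalogReported))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = FALSE)

  invisible(list(beta = p("beta_matrix.tsv"),
                 manifest = p("locus_manifest.bed"),
                 tss = p("tss_table.tsv"),
                 expression = p("expression_matrix.tsv"),
                 probeMap = p("probe_map.tsv"),
                 catalog = p("gwas_catalog.tsv"),
                 supplement = p("gwas_supplement.txt"),
                 gmt = p("pathways.gmt"),
                 truth = p("truth.json"),
                 truthData = truth))
}
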