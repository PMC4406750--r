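test_that("bundle generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- smallConfig(seed = 5L)
  b1 <- simulateBundle(cfg, d1)
  b2 <- simulateBundle(cfg, d2)
  for (f in c("beta_matrix.tsv", "locus_manifest.bed", "tss_table.tsv",
              "expression_matrix.tsv", "probe_map.tsv", "gwas_catalog.tsv",
              "gwas_supplement.txt", "pathways.gmt", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("simulated methylation has the configured structure", {
  cfg <- smallConfig(seed = 2L)
  meth <- simulateMethylation(cfg)
  expect_equal(ncol(meth$beta), sum(cfg@groupsMeth))
  expect_equal(as.integer(table(meth$groups)[names(cfg@groupsMeth)]),
               unname(cfg@groupsMeth))
  expect_true(all(meth$beta >= 0.01 & meth$beta <= 0.99))
  expect_false(anyDuplicated(meth$manifest$locus_id) > 0)
  expect_equal(rownames(meth$beta), meth$manifest$locus_id)

  # every planted gene has at least one locus inside one of its windows,
  # and some loci fall outside every window (distal loci)
  u <- megra:::.simUniverse(cfg)
  windows <- buildPromoterWindows(meth$tss)
  pts <- lociAsGRanges(meth$manifest)
  hits <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
  covered <- unique(S4Vectors::mcols(windows)$gene[S4Vectors::subjectHits(hits)])
  expect_true(all(u$plantedDmg %in% covered))
  expect_lt(length(unique(S4Vectors::queryHits(hits))), length(pts))

  # multi-TSS genes exist and produce several windows
  perGene <- table(meth$tss$gene)
  expect_gt(max(perGene), 1)

  # planted effect: RA group mean exceeds OA/NL by about deltaBeta at the
  # planted locus of a planted-only gene
  g <- setdiff(u$plantedDmg, u$plantedDeg)[1]
  w <- windows[S4Vectors::mcols(windows)$gene == g]
  locIn <- names(pts)[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(pts, w, ignore.strand = TRUE))]
  ra <- rowMeans(meth$beta[locIn, meth$groups == "RA", drop = FALSE])
  oa <- rowMeans(meth$beta[locIn, meth$groups == "OA", drop = FALSE])
  expect_gt(max(ra - oa), cfg@deltaBeta * 0.6)
})

test_that("simulated expression plants fold changes on one probe per gene", {
  cfg <- smallConfig(seed = 3L)
  expr <- simulateExpression(cfg)
  expect_true(all(expr$intensity > 0))
  expect_equal(ncol(expr$intensity), sum(cfg@groupsExpr))
  expect_true(any(expr$probeMap$gene == ""))  # unmapped probes retained

  u <- megra:::.simUniverse(cfg)
  multi <- names(which(table(expr$probeMap$gene[nzchar(expr$probeMap$gene)]) > 1))
  g <- intersect(u$plantedDeg, multi)[1]
  probes <- expr$probeMap$probe_id[expr$probeMap$gene == g]
  ra <- rowMeans(expr$intensity[probes, expr$groups == "RA", drop = FALSE])
  oa <- rowMeans(expr$intensity[probes, expr$groups == "OA", drop = FALSE])
  ratio <- ra / oa
  expect_gt(max(ratio), cfg@foldChangeDeg * 0.7)  # the planted probe
  expect_lt(min(ratio), 1.5)                      # its null siblings
})

test_that("simulated GWAS catalog yields the configured trait gene set", {
  cfg <- smallConfig(seed = 4L)
  gw <- simulateGwasCatalog(cfg)
  d <- withr::local_tempdir()
  utils::write.table(gw$catalog, file.path(d, "cat.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  catalog <- readGwasCatalog(file.path(d, "cat.tsv"))
  genes <- extractTraitGenes(catalog, "rheumatoid arthritis", gw$supplement)
  expect_length(genes, cfg@gwasTraitGenes)
  # multi-gene and placeholder cells are present in the dialect
  expect_true(any(grepl(",", gw$catalog$`REPORTED GENE(S)`)))
  expect_true(any(gw$catalog$`REPORTED GENE(S)` %in% c("NR", "intergenic", "-")))
  # supplement genes overlap the catalog only partially
  expect_true(length(setdiff(gw$supplement, catalogBackground(catalog))) > 0)
  # full-size default reproduces the published count of 114 RA GWAS genes
  gwBig <- simulateGwasCatalog(simulationConfig(seed = 1L))
  dd <- withr::local_tempdir()
  utils::write.table(gwBig$catalog, file.path(dd, "cat.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  big <- extractTraitGenes(readGwasCatalog(file.path(dd, "cat.tsv")),
                           "rheumatoid arthritis", gwBig$supplement)
  expect_length(big, 114L)
})

test_that("simulated pathway collection has a controlled planted pathway", {
  cfg <- smallConfig(seed = 6L)
  pw <- simulatePathways(cfg)
  expect_gte(length(pw), 20L)
  planted <- attr(pw, "planted")
  expect_length(pw[[planted]], cfg@plantedPathwaySize)
  expect_length(intersect(pw[[planted]], cfg@plantedTriple),
                cfg@plantedPathwayMegCount)
  sizes <- lengths(pw[setdiff(names(pw), planted)])
  expect_true(all(sizes >= 30 & sizes <= 300))
})
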