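writeCatalog <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c("DISEASE/TRAIT\tSNPS\tP-VALUE\tREPORTED GENE(S)", lines), f)
  f
}

test_that("catalog parsing handles multi-gene cells, placeholders and bad rows", {
  f <- writeCatalog(c(
    "Rheumatoid arthritis\trs1\t5E-08\tTNF, IL6",
    "Rheumatoid arthritis (ACPA-positive)\trs2\t2E-09\tptpn22; STAT4",
    "Rheumatoid arthritis\trs3\t1E-08\tNR",
    "Type 2 diabetes\trs4\t3E-10\tTCF7L2",
    "Height\trs5\t1E-12\tintergenic",
    "Crohn's disease\trs6\t4E-09\t-",
    "Asthma\trs7\t9E-07\t",
    "broken row without enough fields"))
  expect_warning(cat <- readGwasCatalog(f), "malformed")
  expect_equal(nrow(cat), 7L)
  expect_equal(cat$reported_genes[[1]], c("TNF", "IL6"))
  expect_equal(cat$reported_genes[[2]], c("PTPN22", "STAT4"))  # normalized
  expect_length(cat$reported_genes[[3]], 0L)
  expect_length(cat$reported_genes[[5]], 0L)
  expect_length(cat$reported_genes[[7]], 0L)
})

test_that("trait gene extraction matches patterns and deduplicates with the supplement", {
  f <- writeCatalog(c(
    "Rheumatoid arthritis\trs1\t5E-08\tTNF, IL6",
    "Rheumatoid arthritis severity\trs2\t2E-09\tSTAT4",
    "rheumatoid ARTHRITIS\trs8\t1E-09\tTNF",
    "Type 2 diabetes\trs4\t3E-10\tTCF7L2"))
  cat <- readGwasCatalog(f)
  expect_equal(extractTraitGenes(cat, "rheumatoid arthritis"),
               c("IL6", "STAT4", "TNF"))
  # supplement genes are unioned and duplicates collapse
  expect_equal(extractTraitGenes(cat, "rheumatoid arthritis",
                                 supplement = c("TNF", "ELMO1")),
               c("ELMO1", "IL6", "STAT4", "TNF"))
  # exact mode drops the qualified trait spellings
  expect_equal(extractTraitGenes(cat, "Rheumatoid arthritis", exact = TRUE),
               c("IL6", "TNF"))
  expect_equal(extractTraitGenes(cat, "no such trait"), character(0))
  expect_error(extractTraitGenes(cat, character(0)), "pattern")
})

test_that("catalog background covers every trait and contains the catalog RA genes", {
  f <- writeCatalog(c(
    "Rheumatoid arthritis\trs1\t5E-08\tTNF, IL6",
    "Type 2 diabetes\trs4\t3E-10\tTCF7L2",
    "Height\trs5\t1E-12\tintergenic"))
  cat <- readGwasCatalog(f)
  bg <- catalogBackground(cat)
  expect_equal(bg, c("IL6", "TCF7L2", "TNF"))
  ra <- extractTraitGenes(cat, "rheumatoid arthritis")
  expect_true(all(ra %in% bg))
})

test_that("parsing is idempotent under re-serialization", {
  cfg <- smallConfig(seed = 12L)
  gw <- simulateGwasCatalog(cfg)
  d <- withr::local_tempdir()
  utils::write.table(gw$catalog, file.path(d, "a.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c1 <- readGwasCatalog(file.path(d, "a.tsv"))
  # re-serialize the parsed form and re-read
  out <- data.frame(`DISEASE/TRAIT` = c1$trait, SNPS = c1$snps,
                    `P-VALUE` = c1$p_value,
                    `REPORTED GENE(S)` = vapply(c1$reported_genes, paste,
                                                character(1), collapse = ", "),
                    check.names = FALSE)
  utils::write.table(out, file.path(d, "b.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c2 <- readGwasCatalog(file.path(d, "b.tsv"))
  expect_equal(c1$trait, c2$trait)
  expect_equal(c1$reported_genes, c2$reported_genes)
  # superset property on the simulated catalog (catalog-only extraction)
  expect_true(all(extractTraitGenes(c1, "rheumatoid arthritis") %in%
                    catalogBackground(c1)))
})
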