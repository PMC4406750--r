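test_that("locus calling enforces both the q-value and mean-difference filters", {
  # 40 null loci + 3 crafted loci: strong shift, sub-threshold shift,
  # strong shift diluted by noise so its q stays above threshold
  set.seed(21)
  n1 <- 6; n2 <- 6
  beta <- matrix(runif(40 * (n1 + n2), 0.4, 0.6), nrow = 40)
  strong <- c(rep(0.2, n1), rep(0.7, n2))
  weak <- c(rep(0.50, n1), rep(0.55, n2)) + rnorm(n1 + n2, 0, 0.004)
  beta <- rbind(beta, strong, weak)
  rownames(beta) <- c(sprintf("cg%02d", 1:40), "strong", "weak")
  groups <- rep(c("RA", "OA"), c(n1, n2))

  rec <- testAllLoci(beta, groups, c("RA", "OA"))
  expect_equal(nrow(rec), nrow(beta))
  # the calling rule is exactly q < 0.05 AND |delta| > 0.1
  expect_equal(rec$is_dml, rec$q_value < 0.05 & abs(rec$delta) > 0.1)
  sr <- rec[rec$locus_id == "strong", ]
  wr <- rec[rec$locus_id == "weak", ]
  expect_true(sr$is_dml)
  expect_lt(wr$q_value, 0.05)       # significant ...
  expect_lt(abs(wr$delta), 0.1)     # ... but fails the mean-difference filter
  expect_false(wr$is_dml)
  expect_equal(rec$delta, rec$mean_a - rec$mean_b)

  expect_error(testAllLoci(beta, groups, c("RA", "NL")), ">= 2 samples")
  betaNA <- beta; betaNA[1, 1] <- NA
  expect_message(recNA <- testAllLoci(betaNA, groups, c("RA", "OA")),
                 "skipped")
  expect_equal(nrow(recNA), nrow(beta) - 1L)
})

test_that("promoter windows are strand-aware -2500/+500 half-open intervals", {
  tss <- data.frame(gene = c("GPLUS", "GMINUS", "GMULTI", "GMULTI"),
                    chrom = "chr1", strand = c("+", "-", "+", "+"),
                    tss_position = c(10000L, 10000L, 10000L, 50000L),
                    transcript_label = c("v1", "v1", "v1", "v2"))
  w <- buildPromoterWindows(tss)
  expect_true(all(GenomicRanges::width(w) == 3000L))
  # + strand: [7500, 10500) zero-based -> 7501..10500 one-based
  expect_equal(GenomicRanges::start(w[1]), 7501L)
  expect_equal(GenomicRanges::end(w[1]), 10500L)
  # - strand: [9500, 12500) zero-based
  expect_equal(GenomicRanges::start(w[2]), 9501L)
  expect_equal(GenomicRanges::end(w[2]), 12500L)
  expect_equal(sum(S4Vectors::mcols(w)$gene == "GMULTI"), 2L)
  tssBad <- tss; tssBad$strand[1] <- "*"
  expect_error(buildPromoterWindows(tssBad), "strand")
})

test_that("locus-to-gene mapping honours half-open window boundaries", {
  tss <- data.frame(gene = "GPLUS", chrom = "chr1", strand = "+",
                    tss_position = 10000L, transcript_label = "v1")
  w <- buildPromoterWindows(tss)
  manifest <- data.frame(chrom = "chr1",
                         start = c(7500L, 10499L, 10500L, 7499L),
                         end = c(7502L, 10501L, 10502L, 7501L),
                         locus_id = c("atStart", "lastIn", "atEnd", "before"))
  mkRec <- function(ids) data.frame(locus_id = manifest$locus_id,
                                    is_dml = manifest$locus_id %in% ids)
  expect_equal(dmlToDmg(mkRec("atStart"), w, manifest), "GPLUS")
  expect_equal(dmlToDmg(mkRec("lastIn"), w, manifest), "GPLUS")
  expect_equal(dmlToDmg(mkRec("atEnd"), w, manifest), character(0))
  expect_equal(dmlToDmg(mkRec("before"), w, manifest), character(0))
  expect_equal(dmlToDmg(mkRec(character(0)), w, manifest), character(0))
  expect_error(dmlToDmg(data.frame(locus_id = "ghost", is_dml = TRUE),
                        w, manifest), "absent from manifest")
})

test_that("locus-to-gene mapping equals a brute-force double loop", {
  set.seed(31)
  nGenes <- 40; nLoci <- 800
  tss <- data.frame(gene = sprintf("G%02d", seq_len(nGenes)),
                    chrom = sample(c("chr1", "chr2"), nGenes, TRUE),
                    strand = sample(c("+", "-"), nGenes, TRUE),
                    tss_position = sample(5000:200000, nGenes),
                    transcript_label = "v1")
  w <- buildPromoterWindows(tss)
  manifest <- data.frame(chrom = sample(c("chr1", "chr2"), nLoci, TRUE),
                         start = sample(0:210000, nLoci),
                         locus_id = sprintf("cg%04d", seq_len(nLoci)))
  manifest$end <- manifest$start + 2L
  rec <- data.frame(locus_id = manifest$locus_id,
                    is_dml = runif(nLoci) < 0.3)
  got <- dmlToDmg(rec, w, manifest)

  plus <- tss$strand == "+"
  ws <- ifelse(plus, tss$tss_position - 2500L, tss$tss_position - 500L)
  we <- ifelse(plus, tss$tss_position + 500L, tss$tss_position + 2500L)
  expected <- character(0)
  for (i in which(rec$is_dml)) {
    s <- manifest$start[i]
    for (j in seq_len(nGenes)) {
      if (manifest$chrom[i] == tss$chrom[j] && s >= ws[j] && s < we[j])
        expected <- c(expected, tss$gene[j])
    }
  }
  expect_equal(got, sort(unique(expected)))
})

test_that("combined gene sets are unions over comparisons", {
  expect_equal(combineGeneSets(list(c("A", "B"), c("B", "C"))),
               c("A", "B", "C"))
  expect_equal(combineGeneSets(list(c("B", "A"))), c("A", "B"))
  expect_equal(combineGeneSets(list()), character(0))
})

test_that("planted DMGs are recovered on the synthetic bundle and the
           background always contains the combined set", {
  cfg <- smallConfig(seed = 8L)
  meth <- simulateMethylation(cfg)
  res <- callDmg(meth$beta, meth$groups, meth$manifest, meth$tss)
  u <- megra:::.simUniverse(cfg)
  expect_gte(length(intersect(res$combined, u$plantedDmg)),
             ceiling(0.95 * length(u$plantedDmg)))
  windows <- buildPromoterWindows(meth$tss)
  bg <- methylationBackground(meth$manifest, windows,
                              max(1L, length(res$combined)))
  expect_true(all(res$combined %in% backgroundGenes(bg)))
})
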