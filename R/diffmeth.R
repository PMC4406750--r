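#' Test all methylation loci of one group comparison
#'
#' Welch t-tests on beta values for every locus, comparing the first group
#' against the second. q-values are Benjamini-Hochberg adjusted across all
#' loci of this comparison (each comparison is its own family of tests). A
#' locus is differentially methylated (DML) when `q < qThreshold` and the
#' absolute group mean difference exceeds `deltaThreshold` (defaults: the
#' q < 0.05 and |delta| > 0.1 calling rule). Loci containing missing values
#' are skipped with a message.
#'
#' @param beta Numeric loci x samples matrix of beta values.
#' @param groups Factor (or character) of group labels, one per column.
#' @param comparison Length-2 character vector: first vs second group.
#' @param qThreshold,deltaThreshold Calling thresholds (strict
#'   inequalities).
#' @return A data.frame with one row per tested locus: `locus_id`,
#'   `comparison`, `mean_a`, `mean_b`, `delta`, `t_stat`, `df`, `p_value`,
#'   `q_value`, `is_dml`.
#' @export
testAllLoci <- function(beta, groups, comparison,
                        qThreshold = 0.05, deltaThreshold = 0.1) {
  stopifnot(length(comparison) == 2L)
  groups <- as.character(groups)
  ia <- which(groups == comparison[1])
  ib <- which(groups == comparison[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("testAllLoci: both comparison groups need >= 2 samples")
  sub <- beta[, c(ia, ib), drop = FALSE]
  complete <- stats::complete.cases(sub)
  if (any(!complete))
    message(sum(!complete), " locus/loci with missing values skipped")
  sub <- sub[complete, , drop = FALSE]
  res <- rowWelchTests(sub[, seq_along(ia), drop = FALSE],
                       sub[, length(ia) + seq_along(ib), drop = FALSE])
  res$q_value <- bhAdjust(res$p_value)
  res$is_dml <- res$q_value < qThreshold & abs(res$delta) > deltaThreshold
  data.frame(locus_id = rownames(sub),
             comparison = paste(comparison, collapse = "_vs_"),
             res, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build promoter windows around every TSS
#'
#' One window per TSS row, measured in the transcription direction:
#' `upstream` bases before the TSS through `downstream` bases after it
#' (defaults -2500/+500, a 3000-bp window). In 0-based half-open genome
#' coordinates a plus-strand TSS at t yields \[t-2500, t+500) and a
#' minus-strand TSS \[t-500, t+2500); genes with several TSSs yield several
#' (possibly overlapping) windows.
#'
#' @param tss TSS table data.frame (see [readTssTable()]).
#' @param upstream,downstream Window extent in transcription direction.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene` and
#'   `source_tss`.
#' @export
buildPromoterWindows <- function(tss, upstream = 2500L, downstream = 500L) {
  bad <- setdiff(unique(tss$strand), c("+", "-"))
  if (length(bad))
    stop("buildPromoterWindows: unknown strand symbol(s): ",
         paste(bad, collapse = ", "))
  t0 <- tss$tss_position
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, t0 - upstream, t0 - downstream)
  end0 <- ifelse(plus, t0 + downstream, t0 + upstream)
  gr <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = tss$strand,
    gene = normalizeSymbols(tss$gene),
    source_tss = t0)
  gr
}

#' Map differentially methylated loci to genes
#'
#' A gene is differentially methylated (DMG) when at least one DML lies
#' inside any of its promoter windows; membership is decided by the locus
#' start position (half-open window semantics: a locus at the window start
#' is inside, one at the window end is outside).
#'
#' @param dmlRecords Output of [testAllLoci()].
#' @param windows Promoter windows from [buildPromoterWindows()].
#' @param manifest Locus manifest data.frame; every DML locus must be
#'   present (a missing one is a data inconsistency and a hard error).
#' @return Sorted character vector of DMG symbols.
#' @export
dmlToDmg <- function(dmlRecords, windows, manifest) {
  sig <- dmlRecords$locus_id[dmlRecords$is_dml]
  if (!length(sig)) return(character(0))
  miss <- setdiff(sig, manifest$locus_id)
  if (length(miss))
    stop("dmlToDmg: DML loci absent from manifest: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pts <- lociAsGRanges(manifest[manifest$locus_id %in% sig, , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
  sort(unique(S4Vectors::mcols(windows)$gene[S4Vectors::subjectHits(hits)]))
}

#' Union of per-comparison gene sets
#'
#' The combined DMG (or DEG) set is the union over all comparisons run:
#' every gene identified in at least one comparison is retained.
#'
#' @param sets List of character vectors.
#' @return Sorted unique union.
#' @export
combineGeneSets <- function(sets) {
  sort(unique(as.character(unlist(sets, use.names = FALSE))))
}

#' Call differentially methylated genes across comparisons
#'
#' Convenience wrapper running [testAllLoci()] for each comparison (default
#' RA vs OA and RA vs NL), mapping DMLs into promoter windows with
#' [dmlToDmg()] and combining the per-comparison DMG sets by union.
#'
#' @inheritParams testAllLoci
#' @param manifest Locus manifest data.frame.
#' @param tss TSS table data.frame.
#' @param comparisons List of length-2 character vectors.
#' @param upstream,downstream Promoter window extent.
#' @return A list with `dml` (per-comparison record tables),
#'   `perComparison` (per-comparison DMG sets) and `combined` (their
#'   union).
#' @export
callDmg <- function(beta, groups, manifest, tss,
                    comparisons = list(c("RA", "OA"), c("RA", "NL")),
                    qThreshold = 0.05, deltaThreshold = 0.1,
                    upstream = 2500L, downstream = 500L) {
  windows <- buildPromoterWindows(tss, upstream, downstream)
  dml <- lapply(comparisons, function(cmp)
    testAllLoci(beta, groups, cmp, qThreshold, deltaThreshold))
  names(dml) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  per <- lapply(dml, dmlToDmg, windows = windows, manifest = manifest)
  list(dml = dml, perComparison = per, combined = combineGeneSets(per))
}
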