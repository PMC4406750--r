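#' Test all expression probes of one group comparison
#'
#' Welch t-tests per probe. Probes of the same gene are tested separately
#' (never averaged), because distinct probes may interrogate distinct exons
#' or transcript variants. The test runs on log2-transformed intensities
#' (variance stabilization; set `testScale = "linear"` to test raw values),
#' while the fold change is the symmetric ratio of linear-scale group means:
#' `max(m1/m2, m2/m1)`. A probe is differentially expressed when
#' `fold_change > foldThreshold` and the uncorrected `p < pThreshold`
#' (defaults: the >2-fold, p < 0.05 rule; no multiple-testing correction is
#' applied at this stage). Probes without a gene mapping are retained and
#' flagged with an empty `gene`.
#'
#' @param intensity Positive probes x samples matrix of linear-scale
#'   intensities (set `log2Input = TRUE` if already log2).
#' @param probeMap data.frame with columns `probe_id`, `gene` (empty string
#'   for unmapped probes).
#' @param groups Factor (or character) of group labels, one per column.
#' @param comparison Length-2 character vector: first vs second group.
#' @param foldThreshold,pThreshold Calling thresholds (strict
#'   inequalities).
#' @param log2Input Set TRUE when the matrix is already log2 scale; linear
#'   means are then recovered by exponentiation for the fold change.
#' @param testScale `"log2"` (default) or `"linear"` scale for the Welch
#'   test.
#' @return A data.frame with one row per probe: `probe_id`, `gene`,
#'   `comparison`, `mean_a`, `mean_b` (linear scale), `fold_change`,
#'   `t_stat`, `df`, `p_value`, `is_deg_probe`.
#' @export
testAllProbes <- function(intensity, probeMap, groups, comparison,
                          foldThreshold = 2, pThreshold = 0.05,
                          log2Input = FALSE, testScale = c("log2", "linear")) {
  testScale <- match.arg(testScale)
  stopifnot(length(comparison) == 2L)
  groups <- as.character(groups)
  ia <- which(groups == comparison[1])
  ib <- which(groups == comparison[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("testAllProbes: both comparison groups need >= 2 samples")
  lin <- if (log2Input) 2^intensity else intensity
  if (any(lin <= 0))
    stop("testAllProbes: nonpositive intensities are incompatible with a linear fold change")
  testMat <- if (testScale == "log2") log2(lin) else lin
  res <- rowWelchTests(testMat[, ia, drop = FALSE],
                       testMat[, ib, drop = FALSE])
  linA <- rowMeans(lin[, ia, drop = FALSE])
  linB <- rowMeans(lin[, ib, drop = FALSE])
  fold <- pmax(linA / linB, linB / linA)
  gene <- probeMap$gene[match(rownames(intensity), probeMap$probe_id)]
  gene[is.na(gene)] <- ""
  data.frame(probe_id = rownames(intensity),
             gene = gene,
             comparison = paste(comparison, collapse = "_vs_"),
             mean_a = linA, mean_b = linB,
             fold_change = fold,
             t_stat = res$t_stat, df = res$df, p_value = res$p_value,
             is_deg_probe = fold > foldThreshold & res$p_value < pThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse probe calls to differentially expressed genes
#'
#' The any-probe rule: a gene is differentially expressed (DEG) when at
#' least one of its probes passes the probe-level filters. Unmapped probes
#' (empty gene) contribute no gene.
#'
#' @param records Output of [testAllProbes()].
#' @return Sorted character vector of DEG symbols.
#' @export
probesToDeg <- function(records) {
  g <- records$gene[records$is_deg_probe]
  sort(unique(g[nzchar(g)]))
}

#' Call differentially expressed genes across comparisons
#'
#' Runs [testAllProbes()] for each comparison (default RA vs OA and RA vs
#' NL), applies the any-probe rule per comparison and combines the
#' per-comparison DEG sets by union.
#'
#' @inheritParams testAllProbes
#' @param comparisons List of length-2 character vectors.
#' @return A list with `probes` (per-comparison record tables),
#'   `perComparison` (per-comparison DEG sets) and `combined` (their
#'   union).
#' @export
callDeg <- function(intensity, probeMap, groups,
                    comparisons = list(c("RA", "OA"), c("RA", "NL")),
                    foldThreshold = 2, pThreshold = 0.05,
                    log2Input = FALSE, testScale = c("log2", "linear")) {
  testScale <- match.arg(testScale)
  recs <- lapply(comparisons, function(cmp)
    testAllProbes(intensity, probeMap, groups, cmp, foldThreshold,
                  pThreshold, log2Input, testScale))
  names(recs) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  per <- lapply(recs, probesToDeg)
  list(probes = recs, perComparison = per, combined = combineGeneSets(per))
}
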