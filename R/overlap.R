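#' Construct an assay background
#'
#' An identifiable-gene background: every gene the assay could in principle
#' have flagged, plus the number of genes it actually flagged (the
#' permutation draw size).
#'
#' @param label Assay label (e.g. `"methylation"`).
#' @param genes Character vector of identifiable gene symbols.
#' @param drawSize Observed evidence-set size for the assay.
#' @param x An `AssayBackground` (accessors).
#' @return An [AssayBackground-class] object.
#' @rdname assayBackground
#' @export
assayBackground <- function(label, genes, drawSize) {
  new("AssayBackground", label = label,
      genes = unique(normalizeSymbols(genes)),
      drawSize = as.integer(drawSize))
}

#' @rdname assayBackground
#' @export
setMethod("backgroundGenes", "AssayBackground", function(x) x@genes)

#' @rdname assayBackground
#' @export
setMethod("drawSize", "AssayBackground", function(x) x@drawSize)

setMethod("show", "AssayBackground", function(object) {
  cat("AssayBackground '", object@label, "': ", length(object@genes),
      " identifiable genes, draw size ", object@drawSize, "\n", sep = "")
})

#' Methylation-identifiable background
#'
#' Genes with at least one manifest locus inside at least one of their
#' promoter windows - the genes the promoter methylation analysis could
#' have called. By construction this is a superset of any combined DMG set
#' derived from the same manifest and windows.
#'
#' @param manifest Locus manifest data.frame.
#' @param windows Promoter windows from [buildPromoterWindows()].
#' @param drawSize Observed DMG-set size.
#' @return An [AssayBackground-class] labelled `"methylation"`.
#' @export
methylationBackground <- function(manifest, windows, drawSize) {
  pts <- lociAsGRanges(manifest)
  hits <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
  genes <- unique(S4Vectors::mcols(windows)$gene[S4Vectors::subjectHits(hits)])
  assayBackground("methylation", genes, drawSize)
}

#' Expression-identifiable background
#'
#' All genes with at least one mapped probe on the array.
#'
#' @param probeMap data.frame with columns `probe_id`, `gene`.
#' @param drawSize Observed DEG-set size.
#' @return An [AssayBackground-class] labelled `"expression"`.
#' @export
expressionBackground <- function(probeMap, drawSize) {
  g <- probeMap$gene
  assayBackground("expression", g[nzchar(g)], drawSize)
}

#' GWAS-identifiable background
#'
#' All genes reported anywhere in the catalog, regardless of trait.
#'
#' @param catalog Parsed catalog from [readGwasCatalog()].
#' @param drawSize Observed GWAS gene-set size.
#' @return An [AssayBackground-class] labelled `"gwas"`.
#' @export
gwasBackground <- function(catalog, drawSize) {
  assayBackground("gwas", catalogBackground(catalog), drawSize)
}

#' Permutation test for the k-way gene-set overlap
#'
#' Each round draws, independently for each assay and without replacement,
#' `drawSize` genes from that assay's identifiable background and records
#' the size of the k-way intersection of the draws. The empirical p-value
#' for the observed overlap is `(b + 1) / (n + 1)`, where `b` counts null
#' rounds whose overlap reaches the observed value - the standard valid
#' estimator, whose smallest attainable value at n rounds is
#' `1 / (n + 1)`.
#'
#' @param backgrounds List of two or more [AssayBackground-class] objects.
#' @param observed Observed overlap size.
#' @param nPermutations Number of rounds (default 10,000).
#' @param seed Integer seed for the resampling.
#' @return A [PermutationResult-class] object.
#' @export
permuteOverlap <- function(backgrounds, observed, nPermutations = 10000L,
                           seed = 1L) {
  if (length(backgrounds) < 2L)
    stop("permuteOverlap: need at least two backgrounds")
  if (nPermutations < 1L)
    stop("permuteOverlap: nPermutations must be >= 1")
  observed <- as.integer(observed)
  nPermutations <- as.integer(nPermutations)
  universe <- unique(unlist(lapply(backgrounds, backgroundGenes)))
  idx <- lapply(backgrounds, function(b) match(backgroundGenes(b), universe))
  sizes <- vapply(idx, length, integer(1))
  draws <- vapply(backgrounds, drawSize, integer(1))
  if (any(draws > sizes))
    stop("permuteOverlap: draw size exceeds background size")
  K <- length(backgrounds)
  cnt <- integer(length(universe))
  null <- integer(nPermutations)
  set.seed(as.integer(seed))
  for (r in seq_len(nPermutations)) {
    s <- lapply(seq_len(K), function(j) idx[[j]][sample.int(sizes[j], draws[j])])
    cnt[s[[1L]]] <- 1L
    if (K > 2L)
      for (j in 2:(K - 1L)) cnt[s[[j]]] <- cnt[s[[j]]] + 1L
    null[r] <- sum(cnt[s[[K]]] == K - 1L)
    for (j in seq_len(K - 1L)) cnt[s[[j]]] <- 0L
  }
  tab <- table(null)
  nullCounts <- stats::setNames(as.integer(tab), names(tab))
  p <- (sum(null >= observed) + 1) / (nPermutations + 1)
  new("PermutationResult", observed = observed,
      nPermutations = nPermutations, nullCounts = nullCounts,
      pValue = p, seed = as.integer(seed))
}

#' @param x A [PermutationResult-class].
#' @return `pValue(x)`: the empirical p-value; `nullCounts(x)`: the null
#'   overlap histogram; `observedOverlap(x)`: the observed overlap.
#' @rdname permutationAccessors
#' @name permutationAccessors
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname permutationAccessors
#' @export
setMethod("nullCounts", "PermutationResult", function(x) x@nullCounts)

#' @rdname permutationAccessors
#' @export
setMethod("observedOverlap", "PermutationResult", function(x) x@observed)

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed overlap", object@observed, "over",
      object@nPermutations, "rounds\n")
  cat("  empirical p =", format(object@pValue, digits = 4),
      "(floor", format(1 / (object@nPermutations + 1), digits = 4), ")\n")
  cat("  null overlap range:", names(object@nullCounts)[1], "-",
      utils::tail(names(object@nullCounts), 1), "\n")
})
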