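#' Build the per-gene evidence ledger
#'
#' Combines the three evidence streams into one table covering exactly the
#' union of the input sets, with one boolean flag per stream and the
#' evidence count (1-3). Symbols are normalized and the table is sorted
#' lexicographically so serialized output is deterministic.
#'
#' @param dmg,deg,gwas Character vectors of gene symbols.
#' @return An [EvidenceLedger-class] object.
#' @examples
#' led <- buildLedger(c("A", "B"), c("B", "C"), "B")
#' megSet(led, 3)   # "B"
#' vennCounts(led)
#' @export
buildLedger <- function(dmg, deg, gwas) {
  dmg <- unique(normalizeSymbols(dmg))
  deg <- unique(normalizeSymbols(deg))
  gwas <- unique(normalizeSymbols(gwas))
  genes <- sort(unique(c(dmg, deg, gwas)))
  tb <- data.frame(gene = genes,
                   in_dmg = genes %in% dmg,
                   in_deg = genes %in% deg,
                   in_gwas = genes %in% gwas,
                   stringsAsFactors = FALSE)
  tb$evidence_count <- tb$in_dmg + tb$in_deg + tb$in_gwas
  new("EvidenceLedger", table = tb)
}

#' Multi-evidence gene set
#'
#' Genes carried by at least `minEvidence` of the three evidence streams.
#' `minEvidence = 2` (default) gives the MEG set; `minEvidence = 3` the
#' triple-evidence genes.
#'
#' @param x An [EvidenceLedger-class].
#' @param minEvidence 2 or 3.
#' @return Sorted character vector of gene symbols.
#' @rdname megSet
#' @export
setMethod("megSet", "EvidenceLedger", function(x, minEvidence = 2L) {
  if (length(minEvidence) != 1L || !minEvidence %in% c(2L, 3L))
    stop("megSet: minEvidence must be 2 or 3")
  tb <- x@table
  tb$gene[tb$evidence_count >= minEvidence]
})

#' Venn region counts of the three evidence sets
#'
#' Sizes of the seven exclusive regions of the DMG/DEG/GWAS Venn diagram.
#'
#' @param x An [EvidenceLedger-class].
#' @return Named integer vector with elements `dmg_only`, `deg_only`,
#'   `gwas_only`, `dmg_deg`, `dmg_gwas`, `deg_gwas`, `dmg_deg_gwas`.
#' @rdname vennCounts
#' @export
setMethod("vennCounts", "EvidenceLedger", function(x) {
  tb <- x@table
  reg <- function(d, e, g)
    sum(tb$in_dmg == d & tb$in_deg == e & tb$in_gwas == g)
  c(dmg_only = reg(TRUE, FALSE, FALSE),
    deg_only = reg(FALSE, TRUE, FALSE),
    gwas_only = reg(FALSE, FALSE, TRUE),
    dmg_deg = reg(TRUE, TRUE, FALSE),
    dmg_gwas = reg(TRUE, FALSE, TRUE),
    deg_gwas = reg(FALSE, TRUE, TRUE),
    dmg_deg_gwas = reg(TRUE, TRUE, TRUE))
})

#' Evidence ledger as a data.frame
#'
#' @param x An [EvidenceLedger-class].
#' @return The underlying data.frame (gene, in_dmg, in_deg, in_gwas,
#'   evidence_count).
#' @rdname evidenceTable
#' @export
setMethod("evidenceTable", "EvidenceLedger", function(x) x@table)

setMethod("show", "EvidenceLedger", function(object) {
  tb <- object@table
  cat("EvidenceLedger with", nrow(tb), "genes\n")
  cat("  DMG:", sum(tb$in_dmg), " DEG:", sum(tb$in_deg),
      " GWAS:", sum(tb$in_gwas), "\n")
  cat("  multi-evidence (>=2):", sum(tb$evidence_count >= 2L),
      " triple-evidence:", sum(tb$evidence_count == 3L), "\n")
  triple <- tb$gene[tb$evidence_count == 3L]
  if (length(triple))
    cat("  triple:", paste(utils::head(triple, 10), collapse = ", "),
        if (length(triple) > 10) "..." else "", "\n")
})

#' Write the evidence ledger to TSV
#'
#' One row per gene with the three flags and the evidence count, sorted by
#' gene symbol.
#'
#' @param ledger An [EvidenceLedger-class].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeLedger <- function(ledger, path) {
  utils::write.table(evidenceTable(ledger), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
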