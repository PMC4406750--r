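#' Normalize gene symbols
#'
#' Single normalization choke point applied at every ingest: trim
#' whitespace and uppercase. No alias resolution is attempted.
#'
#' @param x Character vector of symbols.
#' @return Normalized character vector.
#' @export
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

#' Infer sample groups from sample identifiers
#'
#' Sample columns follow the `GROUP_nn` convention (e.g. `RA_03`); the
#' group is the prefix before the first underscore.
#'
#' @param sampleIds Character vector of sample identifiers.
#' @return A named factor of group labels.
#' @export
groupsFromSampleIds <- function(sampleIds) {
  stats::setNames(factor(sub("_.*$", "", sampleIds)), sampleIds)
}

writeMatrixTsv <- function(mat, path, idColumn) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read pipeline input files
#'
#' Readers for each on-disk dialect the pipeline consumes. `readBetaMatrix`
#' and `readExpressionMatrix` read feature-by-sample TSV matrices whose
#' first column holds feature identifiers; `readLocusManifest` reads a
#' header-less 4-column BED-like TSV (chrom, start, end, locus_id; 0-based
#' half-open); `readTssTable` reads the gene-model table (gene, chrom,
#' strand, tss_position, transcript_label; one row per TSS);
#' `readProbeMap` reads the probe-to-gene map; `readGeneList` reads a plain
#' one-symbol-per-line list. Gene symbols are normalized on ingest.
#'
#' @param path File path.
#' @return A matrix (`readBetaMatrix`, `readExpressionMatrix`), data.frame
#'   (`readLocusManifest`, `readTssTable`, `readProbeMap`) or character
#'   vector (`readGeneList`).
#' @name readers
NULL

#' @rdname readers
#' @export
readBetaMatrix <- function(path) readMatrixTsv(path)

#' @rdname readers
#' @export
readExpressionMatrix <- function(path) readMatrixTsv(path)

#' @rdname readers
#' @export
readLocusManifest <- function(path) {
  utils::read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "locus_id"),
                    stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
readTssTable <- function(path) {
  tss <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(tss$strand), c("+", "-"))
  if (length(bad))
    stop("readTssTable: unknown strand symbol(s): ", paste(bad, collapse = ", "))
  tss$gene <- normalizeSymbols(tss$gene)
  tss
}

#' @rdname readers
#' @export
readProbeMap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  pm$gene <- normalizeSymbols(pm$gene)
  pm
}

#' @rdname readers
#' @export
readGeneList <- function(path) {
  x <- normalizeSymbols(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a GWAS-catalog-style table
#'
#' Parses a TSV with header columns `DISEASE/TRAIT`, `SNPS`, `P-VALUE` and
#' `REPORTED GENE(S)`. Rows whose field count disagrees with the header are
#' skipped with a warning. Reported-gene cells are split on commas and
#' semicolons; placeholder tokens (`NR`, `intergenic`, `-`, empty) yield an
#' empty gene list for that row.
#'
#' @param path File path.
#' @return A data.frame with columns `trait`, `snps`, `p_value` and the
#'   list-column `reported_genes` (normalized symbols per row).
#' @export
readGwasCatalog <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("readGwasCatalog: empty file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  need <- c("DISEASE/TRAIT", "SNPS", "P-VALUE", "REPORTED GENE(S)")
  if (!all(need %in% header))
    stop("readGwasCatalog: missing required columns: ",
         paste(setdiff(need, header), collapse = ", "))
  body <- fields[-1]
  # trailing empty fields are dropped by strsplit; pad those rows back
  short1 <- lengths(body) == length(header) - 1L
  body[short1] <- lapply(body[short1], function(f) c(f, ""))
  ok <- lengths(body) == length(header)
  if (any(!ok))
    warning(sum(!ok), " malformed catalog row(s) skipped")
  body <- body[ok]
  col <- function(nm) vapply(body, `[[`, character(1), match(nm, header))
  parseGenes <- function(cell) {
    g <- normalizeSymbols(strsplit(cell, "[,;]")[[1]])
    g[nzchar(g) & !(g %in% c("NR", "INTERGENIC", "-"))]
  }
  data.frame(trait = col("DISEASE/TRAIT"),
             snps = col("SNPS"),
             p_value = col("P-VALUE"),
             reported_genes = I(lapply(col("REPORTED GENE(S)"), parseGenes)),
             stringsAsFactors = FALSE)
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes. Symbols
#' are normalized on read.
#'
#' @param path File path.
#' @param pathways Named list of character vectors; an optional
#'   `attr(, "description")` named character vector supplies the second
#'   column (defaults to the set name).
#' @return `readGmt` returns a named list of character vectors with a
#'   `description` attribute; `writeGmt` returns the path invisibly.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3L
  if (!any(ok)) stop("readGmt: no valid gene-set lines")
  fields <- fields[ok]
  sets <- lapply(fields, function(f) unique(normalizeSymbols(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), names(sets))
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(pathways, path) {
  desc <- attr(pathways, "description")
  if (is.null(desc)) desc <- stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, desc[[nm]], pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a locus manifest to genomic ranges
#'
#' Width-1 ranges anchored at each locus start, converting the manifest's
#' 0-based half-open coordinates to the 1-based closed GRanges convention.
#' Promoter-window membership is decided by the locus start position, so
#' these point ranges are what overlap queries use.
#'
#' @param manifest A manifest data.frame (see [readLocusManifest()]).
#' @return A named [GenomicRanges::GRanges] (names are locus ids).
#' @export
lociAsGRanges <- function(manifest) {
  gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$start + 1L, width = 1L))
  names(gr) <- manifest$locus_id
  gr
}
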