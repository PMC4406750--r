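#' Extract trait-associated genes from a GWAS catalog
#'
#' Collects the reported genes of every catalog row whose trait matches any
#' of the given patterns (case-insensitive substring match by default, or
#' exact trait equality), unions them with a supplementary gene list (e.g.
#' from a meta-analysis) and deduplicates.
#'
#' @param catalog Parsed catalog from [readGwasCatalog()].
#' @param traitPatterns Non-empty character vector of patterns (default
#'   `"rheumatoid arthritis"`).
#' @param supplement Character vector of additional symbols (normalized).
#' @param exact Match the trait exactly (case-insensitive) instead of by
#'   substring.
#' @return Sorted character vector of gene symbols.
#' @export
extractTraitGenes <- function(catalog,
                              traitPatterns = "rheumatoid arthritis",
                              supplement = character(),
                              exact = FALSE) {
  if (!length(traitPatterns))
    stop("extractTraitGenes: at least one trait pattern is required")
  trait <- tolower(catalog$trait)
  pats <- tolower(traitPatterns)
  hit <- if (exact) trait %in% pats
         else Reduce(`|`, lapply(pats, function(p) grepl(p, trait, fixed = TRUE)))
  genes <- unlist(catalog$reported_genes[hit], use.names = FALSE)
  sort(unique(c(genes, normalizeSymbols(supplement))))
}

#' All genes reported anywhere in a GWAS catalog
#'
#' The identifiable-gene background of the GWAS evidence stream: the union
#' of reported genes over every catalog row, regardless of trait.
#'
#' @param catalog Parsed catalog from [readGwasCatalog()].
#' @return Sorted character vector of gene symbols.
#' @export
catalogBackground <- function(catalog) {
  sort(unique(unlist(catalog$reported_genes, use.names = FALSE)))
}
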