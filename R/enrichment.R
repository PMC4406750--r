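#' Hypergeometric pathway enrichment of a gene set
#'
#' For each pathway, counts `K` (pathway genes in the background), `m`
#' (query genes in the background), `k` (their overlap) against a
#' background universe of size `N`, and reports the fold enrichment
#' `(k/m)/(K/N)`, the hypergeometric upper-tail p-value P(X >= k) and the
#' Benjamini-Hochberg q-value across all tested pathways. Query genes
#' outside the background are dropped with a message; pathways with no
#' background member are skipped. By default pathway membership is
#' restricted to the background before counting (`restrictToBackground =
#' FALSE` uses raw pathway sizes for `K` instead). Records are sorted by
#' q-value, then p-value.
#'
#' @param query Character vector of query gene symbols (e.g. the MEG set).
#' @param pathways Named list of character vectors (see [readGmt()]).
#' @param background Character vector: the gene universe.
#' @param restrictToBackground Count `K` inside the background (default) or
#'   as the raw pathway size.
#' @param minPathwaySize Smallest `K` tested (default 1: no silent
#'   filtering).
#' @return A data.frame with columns `pathway`, `k`, `K`, `m`, `N`, `fold`,
#'   `p_hyper`, `q_value`.
#' @export
enrichPathways <- function(query, pathways, background,
                           restrictToBackground = TRUE,
                           minPathwaySize = 1L) {
  if (!length(pathways)) stop("enrichPathways: empty pathway collection")
  if (!length(background)) stop("enrichPathways: empty background")
  background <- unique(normalizeSymbols(background))
  query <- unique(normalizeSymbols(query))
  dropped <- setdiff(query, background)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the background dropped")
  query <- intersect(query, background)
  N <- length(background)
  m <- length(query)
  rows <- lapply(names(pathways), function(nm) {
    pwBg <- intersect(unique(normalizeSymbols(pathways[[nm]])), background)
    K <- if (restrictToBackground) length(pwBg)
         else length(unique(normalizeSymbols(pathways[[nm]])))
    if (length(pwBg) == 0L || K < minPathwaySize) return(NULL)
    k <- length(intersect(query, pwBg))
    data.frame(pathway = nm, k = k, K = K, m = m, N = N,
               fold = if (m > 0L && K > 0L) (k / m) / (K / N) else NA_real_,
               p_hyper = hypergeomUpperTail(N, K, m, k),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    stop("enrichPathways: no pathway overlaps the background")
  rows$q_value <- bhAdjust(rows$p_hyper)
  rows[order(rows$q_value, rows$p_hyper, rows$pathway), , drop = FALSE]
}

#' Filter enrichment records by q-value
#'
#' Keeps pathways with `q_value < qThreshold` (strict), preserving order.
#'
#' @param records Output of [enrichPathways()].
#' @param qThreshold Significance threshold (default 0.05).
#' @return The filtered data.frame.
#' @export
filterSignificant <- function(records, qThreshold = 0.05) {
  records[records$q_value < qThreshold, , drop = FALSE]
}
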