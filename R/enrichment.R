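## Hypergeometric over-representation of the paired target genes.

#' Hypergeometric gene-set over-representation analysis
#'
#' Query genes are first intersected with the collection's universe (genes
#' outside it are dropped with a warning; the effective query size counts
#' retained genes only). Per term the raw p-value is the inclusive upper
#' tail \code{P[X >= k]} of the hypergeometric distribution with population
#' \code{N} (universe), \code{K} successes (term size) and \code{n} draws
#' (query size); BH adjustment is applied across all tested terms.
#'
#' @param query Character vector of gene ids.
#' @param sets A \linkS4class{GeneSetCollection}.
#' @return data.frame with columns \code{term_id}, \code{term_name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{fold_enrichment},
#'   \code{p_raw}, \code{p_adj}, sorted by ascending \code{p_raw}.
#' @export
hypergeometricEnrichment <- function(query, sets) {
  stopifnot(is.character(query) || length(query) == 0L,
            is(sets, "GeneSetCollection"))
  universe <- sets@universe
  if (length(universe) == 0L) .stopf("empty gene universe")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0L)
    .warnf("%d query gene(s) outside the universe were dropped",
           length(dropped))
  query <- intersect(query, universe)
  if (length(query) == 0L)
    .stopf("no query genes remain after intersection with the universe")
  N <- length(universe); n <- length(query)
  res <- do.call(rbind, lapply(names(sets@sets), function(id) {
    members <- sets@sets[[id]]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(term_id = id, term_name = unname(sets@termNames[[id]]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_raw = stats::phyper(k - 1L, K, N - K, n,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- benjaminiHochberg(res$p_raw)
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bubble-plot export of significant terms
#'
#' Filters to BH-adjusted p below \code{alpha} and sorts by adjusted p, the
#' selection visualized as bubble plots in the source analysis.
#'
#' @param results data.frame from \code{\link{hypergeometricEnrichment}}.
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @return data.frame with columns \code{term_id}, \code{term_name},
#'   \code{fold_enrichment}, \code{neg_log10_p_adj}, \code{k}.
#' @export
bubbleExport <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  keep <- results[results$p_adj < alpha, , drop = FALSE]
  keep <- keep[order(keep$p_adj, keep$term_id), , drop = FALSE]
  data.frame(term_id = keep$term_id, term_name = keep$term_name,
             fold_enrichment = keep$fold_enrichment,
             neg_log10_p_adj = -log10(pmax(keep$p_adj,
                                           .Machine$double.xmin)),
             k = keep$k, stringsAsFactors = FALSE, row.names = NULL)
}
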