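## Multi-source target aggregation and anti-correlated pair calling.

#' Aggregate ranked target predictions across databases
#'
#' Records are grouped by (miRNA, gene); only pairs supported by at least
#' \code{minSources} distinct databases are kept, mirroring the
#' at-least-three-databases retrieval rule. The aggregate score is the
#' geometric mean of the within-source ranks over the sources where the pair
#' occurs (lower = stronger support); absent sources carry no penalty beyond
#' the source-count gate. Output is sorted by miRNA, then ascending score.
#'
#' @param targets A \linkS4class{TargetTable}.
#' @param minSources Minimum distinct-source support (default 3).
#' @return An \linkS4class{AggregatedTargets}.
#' @examples
#' tt <- TargetTable(data.frame(
#'   mirna = "miR-1", gene = "GeneA", source = c("DIANA", "PicTar", "TargetScan"),
#'   rank = c(2L, 4L, 8L)))
#' targetRecords(aggregateTargets(tt))  # agg_score = (2*4*8)^(1/3) = 4
#' @export
aggregateTargets <- function(targets, minSources = 3L) {
  stopifnot(is(targets, "TargetTable"))
  if (minSources < 1L) .stopf("minSources must be >= 1")
  r <- targets@records
  if (nrow(r) == 0L) {
    rec <- data.frame(mirna = character(0L), gene = character(0L),
                      n_sources = integer(0L), agg_score = numeric(0L))
    return(new("AggregatedTargets", records = rec,
               minSources = as.integer(minSources)))
  }
  key <- paste(r$mirna, r$gene, sep = "\r")
  grp <- split(seq_len(nrow(r)), key)
  rec <- do.call(rbind, lapply(grp, function(idx) {
    data.frame(mirna = r$mirna[idx[1L]], gene = r$gene[idx[1L]],
               n_sources = length(unique(r$source[idx])),
               agg_score = exp(mean(log(r$rank[idx]))),
               stringsAsFactors = FALSE)
  }))
  rec <- rec[rec$n_sources >= minSources, , drop = FALSE]
  rec <- rec[order(rec$mirna, rec$agg_score, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  new("AggregatedTargets", records = rec, minSources = as.integer(minSources))
}

#' Call anti-correlated miRNA-mRNA pairs within one comparison
#'
#' A pair (m, g) is emitted iff the miRNA and the gene are both called
#' differential in the same comparison, the pair is in the aggregated target
#' table, and their log2 fold changes have strictly opposite signs (the
#' repression sign law). "Inversely correlated" is implemented as strict
#' sign opposition of the point log2FC estimates: with n = 3 per group a
#' sample-level correlation is not estimable, so the sign rule is the
#' operative filter. Output order is deterministic (miRNA, then ascending
#' aggregate score).
#'
#' @param deMirna,deMrna \linkS4class{DEResult} tables for the same
#'   comparison, with statuses filled by \code{\link{callDifferential}}.
#' @param agg An \linkS4class{AggregatedTargets}.
#' @param cmp The \linkS4class{Comparison} both tables were computed for.
#' @return data.frame with columns \code{comparison}, \code{mirna},
#'   \code{mirna_log2fc}, \code{gene}, \code{gene_log2fc}, \code{n_sources},
#'   \code{agg_score}.
#' @export
callPairs <- function(deMirna, deMrna, agg, cmp) {
  stopifnot(is(deMirna, "DEResult"), is(deMrna, "DEResult"),
            is(agg, "AggregatedTargets"), is(cmp, "Comparison"))
  for (tab in list(deMirna, deMrna)) {
    tabCmp <- metadata(tab)$comparison
    if (!is.null(tabCmp) && tabCmp@name != cmp@name)
      .stopf("DE table was computed for '%s', not '%s'", tabCmp@name,
             cmp@name)
  }
  rec <- agg@records
  empty <- data.frame(comparison = character(0L), mirna = character(0L),
                      mirna_log2fc = numeric(0L), gene = character(0L),
                      gene_log2fc = numeric(0L), n_sources = integer(0L),
                      agg_score = numeric(0L), stringsAsFactors = FALSE)
  if (nrow(rec) == 0L) return(empty)
  deM <- rownames(deMirna)[deMirna$status != "ns"]
  deG <- rownames(deMrna)[deMrna$status != "ns"]
  rec <- rec[rec$mirna %in% deM & rec$gene %in% deG, , drop = FALSE]
  if (nrow(rec) == 0L) return(empty)
  fcM <- setNames(deMirna$log2fc, rownames(deMirna))[rec$mirna]
  fcG <- setNames(deMrna$log2fc, rownames(deMrna))[rec$gene]
  keep <- sign(fcM) * sign(fcG) < 0          # ties at 0 never pass
  rec <- rec[keep, , drop = FALSE]
  out <- data.frame(comparison = rep(cmp@name, nrow(rec)),
                    mirna = rec$mirna, mirna_log2fc = unname(fcM[keep]),
                    gene = rec$gene, gene_log2fc = unname(fcG[keep]),
                    n_sources = rec$n_sources, agg_score = rec$agg_score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$agg_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  ## hard invariant: no emitted pair may have concordant signs
  stopifnot(all(out$mirna_log2fc * out$gene_log2fc < 0))
  out
}

#' Unique target genes of a pair set
#'
#' Deduplicated, order-stable gene list for the enrichment stage.
#'
#' @param pairs data.frame from \code{\link{callPairs}}.
#' @return Character vector of unique gene ids.
#' @export
pairGeneSet <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) return(character(0L))
  unique(pairs$gene)
}
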