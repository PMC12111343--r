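## Direction/significance concordance against externally supplied DE tables.

#' Direction concordance with an external DE table
#'
#' Restricts to features called differential in the package's own table,
#' matches them against an external table by feature id (harmonize ids with
#' an alias map beforehand if naming conventions differ), and records per
#' feature both fold changes, both significance flags and the sign
#' agreement. The summary fraction is the mean sign agreement over features
#' where both fold changes are nonzero — it depends only on signs and
#' significance flags, never on magnitudes.
#'
#' @param selfTable A called \linkS4class{DEResult}.
#' @param otherTable data.frame with columns \code{feature}, \code{log2fc},
#'   \code{p_adj} from the external analysis.
#' @param alpha Adjusted-p significance cut for the external table
#'   (default 0.05).
#' @return List with \code{table} (per-feature data.frame),
#'   \code{n_common} and \code{concordant_fraction}.
#' @export
directionConcordance <- function(selfTable, otherTable, alpha = 0.05) {
  stopifnot(is(selfTable, "DEResult"), is.data.frame(otherTable))
  need <- c("feature", "log2fc", "p_adj")
  if (!all(need %in% names(otherTable)))
    .stopf("external table needs columns %s", paste(need, collapse = ", "))
  sig <- rownames(selfTable)[selfTable$status != "ns"]
  common <- intersect(sig, otherTable$feature)
  if (length(common) == 0L) {
    unmatched <- utils::head(sig, 10L)
    .stopf(paste0("no overlap between the significant features and the ",
                  "external table; top unmatched ids: %s"),
           paste(unmatched, collapse = ", "))
  }
  selfFc <- setNames(selfTable$log2fc, rownames(selfTable))[common]
  oIdx <- match(common, otherTable$feature)
  otherFc <- otherTable$log2fc[oIdx]
  tab <- data.frame(
    feature = common,
    log2fc_self = unname(selfFc),
    log2fc_other = otherFc,
    significant_self = TRUE,
    significant_other = otherTable$p_adj[oIdx] < alpha,
    concordant = sign(selfFc) == sign(otherFc),
    stringsAsFactors = FALSE, row.names = NULL)
  both <- tab$log2fc_self != 0 & tab$log2fc_other != 0
  frac <- if (any(both)) mean(tab$concordant[both]) else NA_real_
  list(table = tab, n_common = length(common), concordant_fraction = frac)
}
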