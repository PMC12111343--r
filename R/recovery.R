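## Recovery metrics against planted simulation truth. Used by the
## benchmarking workflow to quantify how well each stage recovers what the
## generator planted.

#' Sensitivity and empirical FDR of DE calls against planted truth
#'
#' A planted effect counts as a recovery target when its planted |log2FC| is
#' at least \code{minEffect} (the generator also plants weaker,
#' half-amplitude effects in secondary contrasts; those are excluded from
#' both the sensitivity denominator and the false-positive count, since a
#' call on a genuinely perturbed feature is not a false discovery).
#' Sensitivity is the fraction of targets called with the correct sign;
#' empirical FDR is the fraction of calls on features with no planted effect
#' at all in that comparison.
#'
#' @param deTable A called \linkS4class{DEResult} for one comparison.
#' @param truth The \linkS4class{SyntheticTruth}.
#' @param comparisonName Name of the comparison (must exist in the truth).
#' @param minEffect Smallest planted |log2FC| counting as a target
#'   (default 1.2, the generator's \code{effectLow}).
#' @return List with \code{n_target}, \code{n_called}, \code{tp}, \code{fp},
#'   \code{sensitivity}, \code{fdr}.
#' @export
deRecovery <- function(deTable, truth, comparisonName, minEffect = 1.2) {
  stopifnot(is(deTable, "DEResult"), is(truth, "SyntheticTruth"))
  if (!comparisonName %in% names(truth@deSets))
    .stopf("comparison '%s' is not in the truth", comparisonName)
  planted <- truth@deSets[[comparisonName]]
  planted <- planted[names(planted) %in% rownames(deTable)]
  targets <- planted[abs(planted) >= minEffect]
  called <- deTable[deTable$status != "ns", , drop = FALSE]
  calledSign <- ifelse(called$status == "up", 1, -1)
  names(calledSign) <- rownames(called)
  tp <- sum(names(targets) %in% names(calledSign) &
              sign(targets) == calledSign[names(targets)], na.rm = TRUE)
  fp <- sum(!names(calledSign) %in% names(planted))
  list(n_target = length(targets), n_called = nrow(called), tp = tp,
       fp = fp,
       sensitivity = if (length(targets) > 0L) tp / length(targets)
         else NA_real_,
       fdr = if (nrow(called) > 0L) fp / nrow(called) else 0)
}

#' Recovery of planted anti-correlated pairs
#'
#' @param pairs data.frame from \code{\link{callPairs}}.
#' @param truth The \linkS4class{SyntheticTruth}.
#' @param comparisonName Name of the comparison.
#' @return List with \code{n_planted}, \code{n_emitted}, \code{recovered},
#'   \code{recovery}, \code{n_decoy} (emitted pairs not planted as edges).
#' @export
pairRecovery <- function(pairs, truth, comparisonName) {
  stopifnot(is.data.frame(pairs), is(truth, "SyntheticTruth"))
  if (!comparisonName %in% names(truth@pairs))
    .stopf("comparison '%s' is not in the truth", comparisonName)
  expected <- truth@pairs[[comparisonName]]
  keyE <- paste(expected$mirna, expected$gene, sep = "\r")
  keyP <- paste(pairs$mirna, pairs$gene, sep = "\r")
  keyEdges <- paste(truth@edges$mirna, truth@edges$gene, sep = "\r")
  recovered <- sum(keyE %in% keyP)
  list(n_planted = nrow(expected), n_emitted = nrow(pairs),
       recovered = recovered,
       recovery = if (nrow(expected) > 0L) recovered / nrow(expected)
         else NA_real_,
       n_decoy = sum(!keyP %in% keyEdges))
}
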