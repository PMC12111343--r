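## Normalization, summarization and variance filtering turning raw matrices
## into the analysis-ready log2 matrix.

#' Quantile-normalize an expression matrix
#'
#' After normalization every column carries the identical sorted value
#' multiset: the across-column mean of order statistics. Ties within a column
#' receive the mean of the reference values at their tied positions. The
#' operation is idempotent.
#'
#' @param m An \linkS4class{ExpressionMatrix} with at least two samples.
#' @return An \linkS4class{ExpressionMatrix} on the same scale.
#' @export
quantileNormalize <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (ncol(m) < 2L)
    .stopf("quantile normalization needs at least 2 samples")
  v <- limma::normalizeQuantiles(exprValues(m), ties = TRUE)
  dimnames(v) <- dimnames(exprValues(m))
  ExpressionMatrix(v, exprScale(m))
}

#' log2-transform a linear-scale matrix
#'
#' Applies \code{log2(x + offset)}; the default offset of 1 guards zeros.
#'
#' @param m A linear-scale \linkS4class{ExpressionMatrix}.
#' @param offset Positive pseudo-count.
#' @return A log2-scale \linkS4class{ExpressionMatrix}.
#' @export
log2Transform <- function(m, offset = 1) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprScale(m) != "linear")
    .stopf("log2Transform expects a linear-scale matrix")
  if (offset <= 0) .stopf("offset must be positive")
  ExpressionMatrix(log2(exprValues(m) + offset), "log2")
}

#' Optional floor-and-shift background adjustment
#'
#' Subtracts a low per-column percentile from each column and clamps at a
#' small positive floor. A coarse stand-in for chip-level background
#' correction on linear intensities; disabled by default in the pipeline.
#'
#' @param m A linear-scale \linkS4class{ExpressionMatrix}.
#' @param percentile Per-column background percentile (default 0.02).
#' @param floor Positive clamp after subtraction.
#' @return A linear-scale \linkS4class{ExpressionMatrix}.
#' @export
floorShiftBackground <- function(m, percentile = 0.02, floor = 1e-3) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprScale(m) != "linear")
    .stopf("background adjustment operates on linear intensities")
  if (percentile < 0 || percentile >= 1) .stopf("percentile outside [0, 1)")
  v <- exprValues(m)
  bg <- apply(v, 2L, stats::quantile, probs = percentile, names = FALSE)
  v <- pmax(sweep(v, 2L, bg, "-"), floor)
  ExpressionMatrix(v, "linear")
}

#' Summarize probe-level values into features by Tukey median polish
#'
#' For every feature, the probe-by-sample submatrix is decomposed by
#' alternately sweeping row and column medians (until the maximum absolute
#' change falls below 1e-6 or 10 iterations); the feature's per-sample value
#' is the overall effect plus the column effect, as in RMA summarization.
#'
#' @param probeValues A log2-scale \linkS4class{ExpressionMatrix} of probes.
#' @param probeMap Named character vector mapping probe id to feature id;
#'   every probe must be mapped and every feature must own at least one
#'   probe.
#' @return A log2-scale \linkS4class{ExpressionMatrix} of features.
#' @export
medianPolishSummarize <- function(probeValues, probeMap) {
  stopifnot(is(probeValues, "ExpressionMatrix"))
  if (exprScale(probeValues) != "log2")
    .stopf("median polish expects log2-scale probe values")
  v <- exprValues(probeValues)
  unmapped <- setdiff(rownames(v), names(probeMap))
  if (length(unmapped) > 0L)
    .stopf("unmapped probe '%s'", unmapped[1L])
  features <- unique(unname(probeMap[rownames(v)]))
  orphan <- setdiff(unique(unname(probeMap)), unname(probeMap[rownames(v)]))
  if (length(orphan) > 0L)
    .stopf("feature '%s' has no probes in the matrix", orphan[1L])
  out <- matrix(NA_real_, length(features), ncol(v),
                dimnames = list(features, colnames(v)))
  for (f in features) {
    sub <- v[rownames(v)[probeMap[rownames(v)] == f], , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[f, ] <- sub[1L, ]
    } else {
      ## the 10-iteration cap is policy; medpolish's non-convergence
      ## warning at that cap is expected, not actionable
      mp <- suppressWarnings(
        stats::medpolish(sub, eps = 1e-6, maxiter = 10L,
                         trace.iter = FALSE, na.rm = FALSE))
      out[f, ] <- mp$overall + mp$col
    }
  }
  ExpressionMatrix(out, "log2")
}

#' Remove low-variance features
#'
#' Drops features whose across-sample variance falls strictly below the
#' \code{quantileCut} empirical quantile of all feature variances. Survivors
#' keep their order and values.
#'
#' @param m A log2-scale \linkS4class{ExpressionMatrix}.
#' @param quantileCut Proportion in [0, 1); 0 keeps everything. The study
#'   names variance filtering without a threshold, so this is an explicit
#'   configuration knob (default 0.25).
#' @return A filtered \linkS4class{ExpressionMatrix}.
#' @export
filterLowVariance <- function(m, quantileCut = 0.25) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (!is.numeric(quantileCut) || quantileCut < 0 || quantileCut >= 1)
    .stopf("quantileCut must lie in [0, 1)")
  if (quantileCut == 0) return(m)
  v <- exprValues(m)
  vars <- apply(v, 1L, stats::var)
  cut <- stats::quantile(vars, quantileCut, names = FALSE)
  keep <- vars >= cut
  ExpressionMatrix(v[keep, , drop = FALSE], exprScale(m))
}
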