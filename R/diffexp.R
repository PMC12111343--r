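## Empirical-Bayes moderated-t differential expression, compound DE calling,
## multiple-testing correction, and ddCt qPCR statistics.

#' Fit the empirical-Bayes variance prior by moment matching
#'
#' Models per-feature sample variances as \code{s^2 ~ s0^2 * F(d_g, d0)} and
#' estimates \code{(d0, s0^2)} from the first two moments of
#' \code{z = log(s^2)}: \code{trigamma(d0/2)} is matched to
#' \code{var(z) - trigamma(d_g/2)} (Newton inversion of the trigamma
#' function, tolerance 1e-8), and \code{log(s0^2)} to
#' \code{mean(z) - digamma(d_g/2) + log(d_g/2) + digamma(d0/2) - log(d0/2)}.
#' When the observed spread of \code{z} does not exceed the sampling
#' contribution \code{trigamma(d_g/2)}, the prior degenerates to full
#' shrinkage: \code{d0 = Inf} with \code{s0^2} set by the mean adjustment
#' alone.
#'
#' @param sSq Numeric vector of per-feature sample variances; non-positive
#'   entries are excluded with a warning.
#' @param dG Residual degrees of freedom, constant across features in the
#'   two-group design.
#' @return A \linkS4class{VariancePrior}.
#' @export
fitVariancePrior <- function(sSq, dG) {
  if (!is.numeric(sSq)) .stopf("sSq must be numeric")
  if (length(dG) != 1L || dG < 1) .stopf("dG must be a single value >= 1")
  bad <- !is.finite(sSq) | sSq <= 0
  if (any(bad)) {
    .warnf("excluding %d feature(s) with non-positive variance from the prior fit",
           sum(bad))
    sSq <- sSq[!bad]
  }
  if (length(sSq) < 2L)
    .stopf("at least 2 positive variances are needed to estimate the prior")
  z <- log(sSq)
  evar <- stats::var(z) - trigamma(dG / 2)
  meanAdj <- mean(z) - digamma(dG / 2) + log(dG / 2)
  if (evar <= 0) {
    return(VariancePrior(d0 = Inf, s0Sq = exp(meanAdj)))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s0Sq <- exp(meanAdj + digamma(d0 / 2) - log(d0 / 2))
  VariancePrior(d0 = d0, s0Sq = s0Sq)
}

## Assemble a DEResult DataFrame from per-feature statistics.
.makeDEResult <- function(features, meanA, meanB, tMod, dfTotal, pRaw, cmp) {
  log2fc <- meanA - meanB
  signedFc <- ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
  res <- DataFrame(mean_a = meanA, mean_b = meanB, log2fc = log2fc,
                   signed_fc = signedFc, t_mod = tMod, df_total = dfTotal,
                   p_raw = pRaw, p_adj = benjaminiHochberg(pRaw),
                   status = rep("ns", length(log2fc)),
                   row.names = features)
  res <- new("DEResult", res)
  metadata(res)$comparison <- cmp
  res
}

#' Moderated two-sample t-test for one comparison
#'
#' For every feature the pooled equal-variance two-sample variance
#' \code{s_g^2} on \code{d_g = n_a + n_b - 2} degrees of freedom is shrunk
#' towards the prior: \code{s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)}, and
#' the moderated statistic \code{t = log2FC / (s~ sqrt(1/n_a + 1/n_b))} is
#' referred to a two-sided t distribution on \code{d0 + d_g} degrees of
#' freedom. \code{d0 = 0} reduces exactly to the ordinary pooled t-test;
#' \code{d0 = Inf} uses the normal limit (t with 1e6 df) for numerical
#' stability. Features with zero pooled variance and zero mean difference
#' get \code{t = 0, p = 1}.
#'
#' @param m A log2-scale \linkS4class{ExpressionMatrix}.
#' @param design A \linkS4class{SampleDesign}; both compared groups need at
#'   least two samples.
#' @param cmp A \linkS4class{Comparison}; positive log2FC means higher in
#'   \code{groupA}.
#' @param prior A \linkS4class{VariancePrior}, or \code{"estimate"} to fit
#'   one from this matrix's pooled variances via
#'   \code{\link{fitVariancePrior}}.
#' @return A \linkS4class{DEResult} (statuses all \code{"ns"}; see
#'   \code{\link{callDifferential}}).
#' @export
moderatedTTest <- function(m, design, cmp, prior = "estimate") {
  stopifnot(is(m, "ExpressionMatrix"), is(design, "SampleDesign"),
            is(cmp, "Comparison"))
  if (exprScale(m) != "log2")
    .stopf("differential expression expects a log2-scale matrix")
  for (g in c(cmp@groupA, cmp@groupB))
    if (!g %in% groupOrder(design))
      .stopf("group '%s' is missing from the design", g)
  sA <- intersect(samplesInGroup(design, cmp@groupA), sampleIds(m))
  sB <- intersect(samplesInGroup(design, cmp@groupB), sampleIds(m))
  if (length(sA) < 2L || length(sB) < 2L)
    .stopf("both groups need at least 2 samples (found %d and %d)",
           length(sA), length(sB))
  v <- exprValues(m)
  xA <- v[, sA, drop = FALSE]; xB <- v[, sB, drop = FALSE]
  nA <- length(sA); nB <- length(sB)
  meanA <- rowMeans(xA); meanB <- rowMeans(xB)
  vA <- rowSums((xA - meanA)^2) / (nA - 1)
  vB <- rowSums((xB - meanB)^2) / (nB - 1)
  dG <- nA + nB - 2
  sgSq <- ((nA - 1) * vA + (nB - 1) * vB) / dG

  if (identical(prior, "estimate")) prior <- fitVariancePrior(sgSq, dG)
  stopifnot(is(prior, "VariancePrior"))
  d0 <- prior@d0
  if (is.infinite(d0)) {
    sTildeSq <- rep(prior@s0Sq, length(sgSq))
    dfTotal <- 1e6
  } else if (d0 == 0) {
    sTildeSq <- sgSq
    dfTotal <- dG
  } else {
    sTildeSq <- (d0 * prior@s0Sq + dG * sgSq) / (d0 + dG)
    dfTotal <- d0 + dG
  }
  se <- sqrt(sTildeSq * (1 / nA + 1 / nB))
  log2fc <- meanA - meanB
  tMod <- ifelse(se > 0, log2fc / se,
                 ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  pRaw <- ifelse(is.finite(tMod), 2 * stats::pt(-abs(tMod), df = dfTotal),
                 0)
  pRaw[se == 0 & log2fc == 0] <- 1
  .makeDEResult(rownames(v), meanA, meanB, tMod, rep(dfTotal, length(tMod)),
                pRaw, cmp)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the standard step-up adjustment
#' (\code{q_(i) = min_{j >= i} m p_(j) / j}, capped at 1, returned in the
#' original order).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return The adjusted p-values.
#' @export
benjaminiHochberg <- function(p) {
  if (!is.numeric(p)) .stopf("p must be numeric")
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential features under the compound cut-off
#'
#' A feature is called \code{up} when \code{log2fc > log2(fcThreshold)} AND
#' \code{p_raw < pThreshold} AND \code{p_adj < fdrLevel}; \code{down} is the
#' mirror; everything else is \code{ns}. The conjunction is the strict
#' reading of "absolute fold change > 2 and p < 0.05 with 20 percent FDR
#' correction". The (down, up) count pair is stored in the result's
#' metadata.
#'
#' @param res A \linkS4class{DEResult}.
#' @param fcThreshold Linear fold-change gate (> 1), default 2.
#' @param pThreshold Raw p-value gate, default 0.05.
#' @param fdrLevel BH-adjusted p-value gate, default 0.20.
#' @return The \linkS4class{DEResult} with statuses filled.
#' @export
callDifferential <- function(res, fcThreshold = 2, pThreshold = 0.05,
                             fdrLevel = 0.20) {
  stopifnot(is(res, "DEResult"))
  if (fcThreshold <= 0 || pThreshold <= 0 || fdrLevel <= 0)
    .stopf("thresholds must be positive")
  gate <- res$p_raw < pThreshold & res$p_adj < fdrLevel
  lfcCut <- log2(fcThreshold)
  status <- rep("ns", nrow(res))
  status[gate & res$log2fc > lfcCut] <- "up"
  status[gate & res$log2fc < -lfcCut] <- "down"
  ## rebuild rather than mutate: in-place column replacement on a validated
  ## DataFrame subclass trips S4Vectors' internal coercion
  df <- as(res, "DFrame")
  df[["status"]] <- status
  out <- new("DEResult", df)
  metadata(out) <- metadata(res)
  metadata(out)$n_up <- sum(status == "up")
  metadata(out)$n_down <- sum(status == "down")
  metadata(out)$thresholds <- list(fc = fcThreshold, p = pThreshold,
                                   fdr = fdrLevel)
  out
}

#' ddCt relative quantification with Student's t-test
#'
#' Per sample, \code{dCt = Ct(gene) - Ct(reference)}; per gene,
#' \code{ddCt = mean dCt(cmpGroup) - mean dCt(refGroup)} and
#' \code{fold = 2^-ddCt}. The p-value is the two-sided equal-variance
#' two-sample Student t-test on the dCt values (identical groups give
#' \code{p = 1}); with fewer than two samples in a group the fold change is
#' still returned but the p-value is \code{NA}.
#'
#' @param ct A \linkS4class{CtTable}.
#' @param refGroup,cmpGroup Group labels of the reference and comparison
#'   condition.
#' @return data.frame with columns \code{gene}, \code{ddct},
#'   \code{fold_change}, \code{p}.
#' @export
qpcrDdct <- function(ct, refGroup, cmpGroup) {
  stopifnot(is(ct, "CtTable"))
  design <- ct@design
  sRef <- intersect(samplesInGroup(design, refGroup), colnames(ct@ct))
  sCmp <- intersect(samplesInGroup(design, cmpGroup), colnames(ct@ct))
  if (length(sRef) == 0L || length(sCmp) == 0L)
    .stopf("both groups must be measured in the Ct table")
  genes <- setdiff(rownames(ct@ct), ct@referenceGene)
  ref <- ct@ct[ct@referenceGene, ]
  out <- lapply(genes, function(g) {
    dct <- ct@ct[g, ] - ref
    dRef <- dct[sRef]; dCmp <- dct[sCmp]
    ddct <- mean(dCmp) - mean(dRef)
    p <- NA_real_
    if (length(dRef) >= 2L && length(dCmp) >= 2L) {
      if (stats::sd(c(dRef - mean(dRef), dCmp - mean(dCmp))) == 0) {
        p <- if (ddct == 0) 1 else 0
      } else {
        p <- stats::t.test(dCmp, dRef, var.equal = TRUE)$p.value
      }
    }
    data.frame(gene = g, ddct = ddct, fold_change = 2^(-ddct), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Volcano-plot export table
#'
#' Lossless projection of a DE table to the columns a volcano plot needs.
#'
#' @param res A \linkS4class{DEResult}.
#' @return data.frame with columns \code{feature}, \code{log2fc},
#'   \code{neg_log10_p_raw}, \code{status}.
#' @export
volcanoTable <- function(res) {
  stopifnot(is(res, "DEResult"))
  data.frame(feature = rownames(res), log2fc = res$log2fc,
             neg_log10_p_raw = -log10(pmax(res$p_raw, .Machine$double.xmin)),
             status = res$status, stringsAsFactors = FALSE)
}
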