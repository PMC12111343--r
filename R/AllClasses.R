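#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

## ---------------------------------------------------------------------------
## ExpressionMatrix
## ---------------------------------------------------------------------------

#' ExpressionMatrix: a features-by-samples expression container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} carrying a single
#' \code{exprs} assay plus a scale tag. \code{scale = "log2"} matrices must be
#' entirely finite; \code{scale = "linear"} matrices must be non-negative.
#' Missing values are rejected in both cases.
#'
#' @slot scale Either \code{"log2"} or \code{"linear"}.
#' @export
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         slots = c(scale = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- tryCatch(assay(object, "exprs"), error = function(e) NULL)
  if (is.null(v)) return("assay 'exprs' is missing")
  if (!is.numeric(v)) return("expression values must be numeric")
  fid <- rownames(v); sid <- colnames(v)
  if (is.null(fid) || is.null(sid))
    return("feature and sample identifiers are required")
  if (anyDuplicated(fid))
    return(sprintf("duplicated feature id '%s'", fid[duplicated(fid)][1L]))
  if (anyDuplicated(sid))
    return(sprintf("duplicated sample id '%s'", sid[duplicated(sid)][1L]))
  if (anyNA(v)) return("missing values are not supported")
  if (!identical(length(object@scale), 1L) ||
      !object@scale %in% c("log2", "linear"))
    return("scale must be 'log2' or 'linear'")
  if (object@scale == "log2" && any(!is.finite(v)))
    return("log2-scale matrices must contain only finite values")
  if (object@scale == "linear" && any(v < 0))
    return("linear-scale matrices must be non-negative")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix with unique rownames (features) and colnames
#'   (samples).
#' @param scale \code{"log2"} or \code{"linear"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(paste0("miR-", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "log2")
#' @export
ExpressionMatrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionMatrix", se, scale = scale)
}

#' @rdname ExpressionMatrix
#' @param x An ExpressionMatrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "exprs"))

#' @rdname ExpressionMatrix
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname ExpressionMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname ExpressionMatrix
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s scale)\n",
              nrow(object), ncol(object), object@scale))
})

## ---------------------------------------------------------------------------
## SampleDesign
## ---------------------------------------------------------------------------

#' SampleDesign: sample-to-group assignment
#'
#' @slot assignments Named character vector, sample id -> group label.
#' @slot groupOrder Ordered character vector of group labels.
#' @export
setClass("SampleDesign",
         slots = c(assignments = "character", groupOrder = "character"))

setValidity("SampleDesign", function(object) {
  a <- object@assignments
  if (length(a) == 0L) return("design has no samples")
  if (is.null(names(a)) || any(names(a) == ""))
    return("every assignment must be named by a sample id")
  if (anyDuplicated(names(a)))
    return(sprintf("sample '%s' listed more than once",
                   names(a)[duplicated(names(a))][1L]))
  if (!all(a %in% object@groupOrder))
    return(sprintf("group '%s' is missing from the group order",
                   setdiff(a, object@groupOrder)[1L]))
  empty <- setdiff(object@groupOrder, a)
  if (length(empty) > 0L)
    return(sprintf("group '%s' has no samples", empty[1L]))
  if (anyDuplicated(object@groupOrder)) return("duplicated group label")
  TRUE
})

#' Construct a SampleDesign
#'
#' @param assignments Named character vector mapping sample ids to group
#'   labels.
#' @param groupOrder Ordered group labels; defaults to order of first
#'   appearance.
#' @return A \linkS4class{SampleDesign}.
#' @export
SampleDesign <- function(assignments, groupOrder = unique(unname(assignments))) {
  new("SampleDesign", assignments = assignments, groupOrder = groupOrder)
}

#' @rdname SampleDesign
#' @param x A SampleDesign.
#' @export
setGeneric("groupOrder", function(x) standardGeneric("groupOrder"))

#' @rdname SampleDesign
#' @export
setMethod("groupOrder", "SampleDesign", function(x) x@groupOrder)

#' @rdname SampleDesign
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname SampleDesign
#' @export
setMethod("assignments", "SampleDesign", function(x) x@assignments)

#' Samples belonging to one group
#' @param design A SampleDesign.
#' @param group A group label.
#' @return Character vector of sample ids.
#' @export
samplesInGroup <- function(design, group) {
  stopifnot(is(design, "SampleDesign"))
  if (!group %in% design@groupOrder)
    .stopf("group '%s' is not present in the design", group)
  names(design@assignments)[design@assignments == group]
}

setMethod("show", "SampleDesign", function(object) {
  tab <- table(factor(object@assignments, levels = object@groupOrder))
  cat(sprintf("SampleDesign: %d samples, %d groups\n",
              length(object@assignments), length(object@groupOrder)))
  cat(paste(sprintf("  %s (n=%d)", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
})

## ---------------------------------------------------------------------------
## Comparison
## ---------------------------------------------------------------------------

#' Comparison: a two-group contrast
#'
#' Positive log2 fold changes mean higher expression in \code{groupA}
#' ("A vs B").
#'
#' @slot name Display name of the contrast.
#' @slot groupA,groupB Group labels being contrasted.
#' @export
setClass("Comparison",
         slots = c(name = "character", groupA = "character",
                   groupB = "character"))

setValidity("Comparison", function(object) {
  if (object@groupA == object@groupB)
    return("the two compared groups must differ")
  if (nchar(object@groupA) == 0L || nchar(object@groupB) == 0L)
    return("group labels must be non-empty")
  TRUE
})

#' @rdname Comparison-class
#' @param groupA,groupB Group labels.
#' @param name Contrast name; defaults to "A vs B".
#' @return A \linkS4class{Comparison}.
#' @export
Comparison <- function(groupA, groupB,
                       name = paste(groupA, "vs", groupB)) {
  new("Comparison", name = name, groupA = groupA, groupB = groupB)
}

setMethod("show", "Comparison", function(object) {
  cat(sprintf("Comparison: %s (%s vs %s)\n",
              object@name, object@groupA, object@groupB))
})

#' The study's seven default contrasts
#'
#' Four treatment-vs-control contrasts plus the three cross-group contrasts
#' (sex difference and the hormone-replacement comparison).
#'
#' @return List of \linkS4class{Comparison} objects.
#' @export
defaultComparisons <- function() {
  list(Comparison("ORX", "Male C"),
       Comparison("ORX+T", "Male C"),
       Comparison("OVX", "Female C"),
       Comparison("OVX+E", "Female C"),
       Comparison("Male C", "Female C"),
       Comparison("ORX", "OVX"),
       Comparison("ORX+T", "OVX+E"))
}

#' @rdname Comparison-class
#' @export
defaultGroups <- function() {
  c("Male C", "Female C", "ORX", "OVX", "ORX+T", "OVX+E")
}

## ---------------------------------------------------------------------------
## TargetTable
## ---------------------------------------------------------------------------

#' TargetTable: per-database ranked miRNA target predictions
#'
#' @slot records data.frame with columns \code{mirna}, \code{gene},
#'   \code{source}, \code{rank}. Within one (source, miRNA) list ranks are
#'   unique integers starting at 1.
#' @export
setClass("TargetTable", slots = c(records = "data.frame"))

setValidity("TargetTable", function(object) {
  r <- object@records
  need <- c("mirna", "gene", "source", "rank")
  if (!all(need %in% names(r)))
    return(sprintf("missing column '%s'", setdiff(need, names(r))[1L]))
  if (nrow(r) == 0L) return(TRUE)
  if (!is.numeric(r$rank) || any(r$rank != round(r$rank)) || any(r$rank < 1))
    return("ranks must be integers >= 1")
  key <- paste(r$mirna, r$gene, r$source, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate record (%s, %s, %s)", d$mirna, d$gene, d$source))
  }
  for (sm in split(r$rank, paste(r$source, r$mirna, sep = "\r"))) {
    if (anyDuplicated(sm)) return("ranks within a (source, miRNA) list must be unique")
    if (min(sm) != 1L) return("ranks within a (source, miRNA) list must start at 1")
  }
  TRUE
})

#' @rdname TargetTable-class
#' @param records data.frame of (mirna, gene, source, rank).
#' @return A \linkS4class{TargetTable}.
#' @export
TargetTable <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0L) records$rank <- as.integer(records$rank)
  new("TargetTable", records = records)
}

#' @rdname TargetTable-class
#' @param x A TargetTable.
#' @export
setGeneric("targetRecords", function(x) standardGeneric("targetRecords"))

#' @rdname TargetTable-class
#' @export
setMethod("targetRecords", "TargetTable", function(x) x@records)

setMethod("show", "TargetTable", function(object) {
  r <- object@records
  cat(sprintf("TargetTable: %d records, %d miRNAs, %d sources\n",
              nrow(r), length(unique(r$mirna)), length(unique(r$source))))
})

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' GeneSetCollection: named gene sets over a gene universe
#'
#' @slot sets Named list of character vectors (term id -> member genes).
#' @slot termNames Named character vector of human-readable term names.
#' @slot universe Character vector; every set is a subset of it.
#' @export
setClass("GeneSetCollection",
         slots = c(sets = "list", termNames = "character",
                   universe = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) == 0L) return("no gene sets")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must have unique term ids")
  if (any(lengths(object@sets) == 0L))
    return(sprintf("term '%s' is empty",
                   names(object@sets)[lengths(object@sets) == 0L][1L]))
  outside <- vapply(object@sets, function(s) any(!s %in% object@universe),
                    logical(1L))
  if (any(outside))
    return(sprintf("term '%s' contains genes outside the universe",
                   names(object@sets)[outside][1L]))
  TRUE
})

#' Construct a GeneSetCollection
#'
#' Sets are harmonized against the universe: genes outside it are dropped. A
#' term emptied by harmonization is an error.
#'
#' @param sets Named list of character vectors.
#' @param termNames Optional named character vector of descriptions.
#' @param universe Optional gene universe; defaults to the union of all sets.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, termNames = NULL, universe = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) s[s %in% universe])
  if (any(lengths(sets) == 0L))
    .stopf("term '%s' has no genes left after harmonization with the universe",
           names(sets)[lengths(sets) == 0L][1L])
  if (is.null(termNames)) {
    termNames <- setNames(names(sets), names(sets))
  } else {
    termNames <- termNames[names(sets)]
    termNames[is.na(termNames)] <- names(sets)[is.na(termNames)]
    names(termNames) <- names(sets)
  }
  new("GeneSetCollection", sets = sets, termNames = termNames,
      universe = universe)
}

#' @rdname GeneSetCollection
#' @param x A GeneSetCollection.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname GeneSetCollection
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d terms, universe of %d genes\n",
              length(object@sets), length(object@universe)))
})

## ---------------------------------------------------------------------------
## CtTable
## ---------------------------------------------------------------------------

#' CtTable: qPCR cycle-threshold measurements
#'
#' @slot ct Numeric matrix, genes x samples, of Ct values (cycles).
#' @slot referenceGene The designated normalizer gene (e.g. RNU1A1).
#' @slot design A \linkS4class{SampleDesign} covering the samples.
#' @export
setClass("CtTable",
         slots = c(ct = "matrix", referenceGene = "character",
                   design = "SampleDesign"))

setValidity("CtTable", function(object) {
  ct <- object@ct
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    return("ct matrix needs gene rownames and sample colnames")
  if (!object@referenceGene %in% rownames(ct))
    return(sprintf("reference gene '%s' is not measured", object@referenceGene))
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0))
    return("Ct values must be finite and > 0")
  missing <- setdiff(colnames(ct), names(object@design@assignments))
  if (length(missing) > 0L)
    return(sprintf("sample '%s' is missing from the design", missing[1L]))
  TRUE
})

#' @rdname CtTable-class
#' @param ct Genes-by-samples numeric matrix of Ct values.
#' @param referenceGene Name of the reference gene row.
#' @param design SampleDesign for the Ct samples.
#' @return A \linkS4class{CtTable}.
#' @export
CtTable <- function(ct, referenceGene, design) {
  new("CtTable", ct = as.matrix(ct), referenceGene = referenceGene,
      design = design)
}

setMethod("show", "CtTable", function(object) {
  cat(sprintf("CtTable: %d genes x %d samples (reference: %s)\n",
              nrow(object@ct), ncol(object@ct), object@referenceGene))
})

## ---------------------------------------------------------------------------
## VariancePrior
## ---------------------------------------------------------------------------

#' VariancePrior: the empirical-Bayes prior on per-feature variances
#'
#' \code{d0 = Inf} encodes full shrinkage to \code{s0Sq}; \code{d0 = 0}
#' disables moderation.
#'
#' @slot d0 Prior degrees of freedom (>= 0, possibly \code{Inf}).
#' @slot s0Sq Prior variance (> 0, squared log2 units).
#' @export
setClass("VariancePrior", slots = c(d0 = "numeric", s0Sq = "numeric"))

setValidity("VariancePrior", function(object) {
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
    return("d0 must be a single value >= 0 (possibly Inf)")
  if (length(object@s0Sq) != 1L || !is.finite(object@s0Sq) ||
      object@s0Sq <= 0)
    return("s0Sq must be a single finite value > 0")
  TRUE
})

#' @rdname VariancePrior-class
#' @param d0 Prior degrees of freedom.
#' @param s0Sq Prior variance.
#' @return A \linkS4class{VariancePrior}.
#' @export
VariancePrior <- function(d0, s0Sq) new("VariancePrior", d0 = d0, s0Sq = s0Sq)

setMethod("show", "VariancePrior", function(object) {
  cat(sprintf("VariancePrior: d0 = %s, s0^2 = %.6g\n",
              format(object@d0), object@s0Sq))
})

## ---------------------------------------------------------------------------
## DEResult
## ---------------------------------------------------------------------------

#' DEResult: per-feature differential-expression statistics
#'
#' A \code{DataFrame} subclass, one row per feature, with columns
#' \code{mean_a}, \code{mean_b}, \code{log2fc}, \code{signed_fc},
#' \code{t_mod}, \code{df_total}, \code{p_raw}, \code{p_adj}, \code{status}.
#' The contrast and, after \code{\link{callDifferential}}, the up/down counts
#' live in \code{metadata()}.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  need <- c("mean_a", "mean_b", "log2fc", "signed_fc", "t_mod", "df_total",
            "p_raw", "p_adj", "status")
  if (!all(need %in% colnames(object)))
    return(sprintf("missing column '%s'", setdiff(need, colnames(object))[1L]))
  if (nrow(object) > 0L) {
    if (any(object$p_raw < 0 | object$p_raw > 1, na.rm = TRUE))
      return("p_raw outside [0, 1]")
    if (any(object$p_adj + 1e-12 < object$p_raw, na.rm = TRUE))
      return("p_adj must be >= p_raw")
    if (!all(object$status %in% c("up", "down", "ns")))
      return("status must be 'up', 'down' or 'ns'")
  }
  TRUE
})

#' @rdname DEResult-class
#' @param x A DEResult.
#' @export
setGeneric("comparisonName", function(x) standardGeneric("comparisonName"))

#' @rdname DEResult-class
#' @export
setMethod("comparisonName", "DEResult", function(x) metadata(x)$comparison@name)

#' Up/down counts of a called DE table
#' @param x A DEResult after \code{\link{callDifferential}}.
#' @return Named integer vector \code{c(down =, up =)}.
#' @export
deCounts <- function(x) {
  stopifnot(is(x, "DEResult"))
  c(down = sum(x$status == "down"), up = sum(x$status == "up"))
}

setMethod("show", "DEResult", function(object) {
  cmp <- metadata(object)$comparison
  if (!is.null(cmp))
    cat(sprintf("DEResult for %s (positive log2FC = higher in %s)\n",
                cmp@name, cmp@groupA))
  n <- deCounts(object)
  cat(sprintf("%d features: %d down, %d up, %d ns\n", nrow(object),
              n[["down"]], n[["up"]], nrow(object) - sum(n)))
  callNextMethod()
})

## ---------------------------------------------------------------------------
## AggregatedTargets
## ---------------------------------------------------------------------------

#' AggregatedTargets: multi-source target support per (miRNA, gene) pair
#'
#' @slot records data.frame with columns \code{mirna}, \code{gene},
#'   \code{n_sources}, \code{agg_score} (geometric mean of within-source
#'   ranks; lower = stronger support).
#' @slot minSources The source-count threshold used to build the table.
#' @export
setClass("AggregatedTargets",
         slots = c(records = "data.frame", minSources = "integer"))

setValidity("AggregatedTargets", function(object) {
  r <- object@records
  need <- c("mirna", "gene", "n_sources", "agg_score")
  if (!all(need %in% names(r)))
    return(sprintf("missing column '%s'", setdiff(need, names(r))[1L]))
  if (nrow(r) > 0L) {
    if (any(r$n_sources < object@minSources))
      return("a record falls below the min_sources threshold")
    if (anyDuplicated(paste(r$mirna, r$gene, sep = "\r")))
      return("duplicate (miRNA, gene) record")
    if (any(r$agg_score <= 0)) return("agg_score must be positive")
  }
  TRUE
})

setMethod("show", "AggregatedTargets", function(object) {
  cat(sprintf("AggregatedTargets: %d (miRNA, gene) pairs (>= %d sources)\n",
              nrow(object@records), object@minSources))
})

#' @rdname AggregatedTargets-class
#' @param x An AggregatedTargets object.
#' @export
setMethod("targetRecords", "AggregatedTargets", function(x) x@records)

## ---------------------------------------------------------------------------
## ClusterModel
## ---------------------------------------------------------------------------

#' ClusterModel: a fitted K-means co-expression model
#'
#' @slot k Number of clusters.
#' @slot centroids k x groups matrix of cluster centres.
#' @slot assignments Named integer vector, feature -> cluster.
#' @slot sse Total within-cluster sum of squared errors.
#' @slot seed,nInit Reproducibility metadata.
#' @slot core List (one element per cluster) of data.frames
#'   \code{(feature, r)} of members correlating with their centroid above the
#'   core threshold; empty until \code{\link{extractCore}} is applied.
#' @export
setClass("ClusterModel",
         slots = c(k = "integer", centroids = "matrix",
                   assignments = "integer", sse = "numeric",
                   seed = "numeric", nInit = "integer", core = "list"))

setValidity("ClusterModel", function(object) {
  if (nrow(object@centroids) != object@k)
    return("centroid count must equal k")
  if (length(object@assignments) > 0L) {
    if (is.null(names(object@assignments)))
      return("assignments must be named by feature")
    if (any(object@assignments < 1L | object@assignments > object@k))
      return("assignment outside 1..k")
  }
  TRUE
})

#' @rdname ClusterModel-class
#' @param x A ClusterModel.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterModel-class
#' @export
setMethod("clusterAssignments", "ClusterModel", function(x) x@assignments)

#' @rdname ClusterModel-class
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname ClusterModel-class
#' @export
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)

#' @rdname ClusterModel-class
#' @export
setGeneric("clusterSse", function(x) standardGeneric("clusterSse"))

#' @rdname ClusterModel-class
#' @export
setMethod("clusterSse", "ClusterModel", function(x) x@sse)

#' @rdname ClusterModel-class
#' @export
setGeneric("coreMembers", function(x) standardGeneric("coreMembers"))

#' @rdname ClusterModel-class
#' @export
setMethod("coreMembers", "ClusterModel", function(x) x@core)

setMethod("show", "ClusterModel", function(object) {
  sizes <- tabulate(object@assignments, nbins = object@k)
  cat(sprintf("ClusterModel: k = %d, sizes = [%s], SSE = %.4g\n",
              object@k, paste(sizes, collapse = ", "), object@sse))
  if (length(object@core) > 0L)
    cat(sprintf("  core members: [%s]\n",
                paste(vapply(object@core, nrow, integer(1L)), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## SimulationParams and SyntheticTruth
## ---------------------------------------------------------------------------

#' SimulationParams: configuration of the synthetic-data generator
#'
#' Defaults emulate the study design: ~700 assayed miRNAs and 5000 mRNAs over
#' six groups (gonadectomy / hormone-replacement design) with three replicates
#' each, log-normal noise on the log2 scale, planted differential miRNAs at
#' |log2FC| between \code{effectLow} and \code{effectHigh}, repressive
#' miRNA-to-mRNA edges with opposite-sign effects, multi-database target
#' support, and two co-expression archetypes (peak in ORX+T; trough in ORX+T
#' with peak in OVX+E).
#'
#' @slot nMirna,nMrna Feature counts.
#' @slot groups Ordered group labels.
#' @slot repsPerGroup Replicates per group (>= 2).
#' @slot baselineMean,baselineSd Per-feature baseline distribution (log2).
#' @slot noiseSd Typical residual standard deviation (log2); per-feature
#'   variances are drawn from a scaled inverse-chi-square with \code{priorDf}
#'   degrees of freedom and scale \code{noiseSd^2}.
#' @slot priorDf Degrees of freedom of the variance prior (default 4).
#' @slot nDeMirnaPerComparison Planted miRNAs per cluster archetype.
#' @slot effectLow,effectHigh Amplitude bounds for planted |log2FC|.
#' @slot targetsPerDeMirna Repressed genes per planted miRNA.
#' @slot nSources Number of target databases emulated.
#' @slot minPlantedSources Minimum source support of planted edges.
#' @slot nTerms Number of gene-set terms emitted.
#' @slot enrichedTermFraction Fraction of terms planted as enriched.
#' @slot decoyFraction Fraction of target-table rows that are decoy edges.
#' @slot repressionJitter Relative jitter of gene vs miRNA effect magnitude.
#' @slot seed RNG seed.
#' @export
setClass("SimulationParams",
         slots = c(nMirna = "integer", nMrna = "integer", groups = "character",
                   repsPerGroup = "integer", baselineMean = "numeric",
                   baselineSd = "numeric", noiseSd = "numeric",
                   priorDf = "numeric", nDeMirnaPerComparison = "integer",
                   effectLow = "numeric", effectHigh = "numeric",
                   targetsPerDeMirna = "integer", nSources = "integer",
                   minPlantedSources = "integer", nTerms = "integer",
                   enrichedTermFraction = "numeric", decoyFraction = "numeric",
                   repressionJitter = "numeric", seed = "numeric"))

setValidity("SimulationParams", function(object) {
  if (object@repsPerGroup < 2L) return("repsPerGroup must be >= 2")
  if (object@effectLow < 1) return("effectLow must be >= 1 to clear the fold gate")
  if (object@effectHigh < object@effectLow) return("effectHigh < effectLow")
  if (object@minPlantedSources > object@nSources)
    return("minPlantedSources must be <= nSources")
  if (object@noiseSd < 0 || object@baselineSd < 0) return("negative sd")
  if (object@decoyFraction < 0 || object@decoyFraction >= 1)
    return("decoyFraction must be in [0, 1)")
  if (object@enrichedTermFraction < 0 || object@enrichedTermFraction > 1)
    return("enrichedTermFraction must be in [0, 1]")
  if (2L * object@nDeMirnaPerComparison > object@nMirna)
    return("too many planted miRNAs for nMirna")
  if (2L * object@nDeMirnaPerComparison * object@targetsPerDeMirna > object@nMrna)
    return("too many planted target genes for nMrna")
  if (length(object@groups) < 2L) return("need >= 2 groups")
  TRUE
})

#' @rdname SimulationParams-class
#' @param nMirna,nMrna,groups,repsPerGroup,baselineMean,baselineSd,noiseSd
#'   See slots.
#' @param priorDf,nDeMirnaPerComparison,effectLow,effectHigh See slots.
#' @param targetsPerDeMirna,nSources,minPlantedSources,nTerms See slots.
#' @param enrichedTermFraction,decoyFraction,repressionJitter,seed See slots.
#' @return A \linkS4class{SimulationParams}.
#' @export
SimulationParams <- function(nMirna = 700L, nMrna = 5000L,
                             groups = defaultGroups(), repsPerGroup = 3L,
                             baselineMean = 7, baselineSd = 1.5,
                             noiseSd = 0.25, priorDf = 4,
                             nDeMirnaPerComparison = 30L,
                             effectLow = 1.2, effectHigh = 2.5,
                             targetsPerDeMirna = 5L, nSources = 5L,
                             minPlantedSources = 3L, nTerms = 40L,
                             enrichedTermFraction = 0.05,
                             decoyFraction = 0.1, repressionJitter = 0.1,
                             seed = 1L) {
  new("SimulationParams", nMirna = as.integer(nMirna),
      nMrna = as.integer(nMrna), groups = groups,
      repsPerGroup = as.integer(repsPerGroup), baselineMean = baselineMean,
      baselineSd = baselineSd, noiseSd = noiseSd, priorDf = priorDf,
      nDeMirnaPerComparison = as.integer(nDeMirnaPerComparison),
      effectLow = effectLow, effectHigh = effectHigh,
      targetsPerDeMirna = as.integer(targetsPerDeMirna),
      nSources = as.integer(nSources),
      minPlantedSources = as.integer(minPlantedSources),
      nTerms = as.integer(nTerms),
      enrichedTermFraction = enrichedTermFraction,
      decoyFraction = decoyFraction, repressionJitter = repressionJitter,
      seed = as.numeric(seed))
}

#' SyntheticTruth: planted ground truth of a simulated dataset
#'
#' @slot deSets Named list (one per comparison) of named numeric vectors of
#'   planted log2 fold changes, covering both miRNAs and genes; only nonzero
#'   planted effects are recorded.
#' @slot edges data.frame of planted repressive edges
#'   \code{(mirna, gene, sign = -1)}.
#' @slot pairs Named list (one per comparison) of data.frames
#'   \code{(mirna, gene)}: the anti-correlated pairs expected to be
#'   recoverable (both members planted at |log2FC| >= effectLow).
#' @slot clusterLabels Named integer vector, miRNA -> archetype (1 or 2);
#'   unplanted miRNAs are absent.
#' @slot enrichedTerms Character vector of planted enriched term ids.
#' @export
setClass("SyntheticTruth",
         slots = c(deSets = "list", edges = "data.frame", pairs = "list",
                   clusterLabels = "integer", enrichedTerms = "character"))

setValidity("SyntheticTruth", function(object) {
  if (nrow(object@edges) > 0L &&
      !all(c("mirna", "gene", "sign") %in% names(object@edges)))
    return("edges need columns mirna, gene, sign")
  if (nrow(object@edges) > 0L && any(object@edges$sign != -1))
    return("planted edges must be repressive (sign -1)")
  TRUE
})

#' @rdname SyntheticTruth-class
#' @param x A SyntheticTruth.
#' @export
setGeneric("plantedDeSets", function(x) standardGeneric("plantedDeSets"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedDeSets", "SyntheticTruth", function(x) x@deSets)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedEdges", function(x) standardGeneric("plantedEdges"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedEdges", "SyntheticTruth", function(x) x@edges)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedPairs", "SyntheticTruth", function(x) x@pairs)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("clusterLabels", "SyntheticTruth", function(x) x@clusterLabels)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("enrichedTerms", function(x) standardGeneric("enrichedTerms"))

#' @rdname SyntheticTruth-class
#' @export
setMethod("enrichedTerms", "SyntheticTruth", function(x) x@enrichedTerms)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d comparisons with planted effects, ",
                     "%d edges, %d labelled miRNAs, %d enriched terms\n"),
              length(object@deSets), nrow(object@edges),
              length(object@clusterLabels), length(object@enrichedTerms)))
})
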