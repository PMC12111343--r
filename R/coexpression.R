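## K-means co-expression clustering of regulated miRNAs on group-mean
## profiles: SSE-vs-k elbow, multi-start Lloyd fits, core-member extraction
## and heatmap / PCA exports.

#' Features significantly regulated in at least one comparison
#'
#' @param deTables List of called \linkS4class{DEResult} tables.
#' @return Character vector (stable order of first appearance).
#' @export
selectClusteringFeatures <- function(deTables) {
  stopifnot(is.list(deTables), length(deTables) >= 1L)
  out <- character(0L)
  for (tab in deTables) {
    stopifnot(is(tab, "DEResult"))
    out <- c(out, rownames(tab)[tab$status != "ns"])
  }
  unique(out)
}

#' Group-mean expression profiles
#'
#' Arithmetic mean per experimental group on the log2 scale, the substrate
#' the clustering operates on.
#'
#' @param m A log2-scale \linkS4class{ExpressionMatrix}.
#' @param design A \linkS4class{SampleDesign}.
#' @param features Features to keep (default: all); unknown ids are errors.
#' @return Numeric matrix, features x groups.
#' @export
groupMeanProfile <- function(m, design, features = NULL) {
  stopifnot(is(m, "ExpressionMatrix"), is(design, "SampleDesign"))
  v <- exprValues(m)
  if (is.null(features)) features <- rownames(v)
  unknown <- setdiff(features, rownames(v))
  if (length(unknown) > 0L)
    .stopf("unknown feature '%s'", unknown[1L])
  groups <- groupOrder(design)
  out <- vapply(groups, function(g) {
    cols <- intersect(samplesInGroup(design, g), colnames(v))
    if (length(cols) == 0L) .stopf("group '%s' has no samples in the matrix", g)
    rowMeans(v[features, cols, drop = FALSE])
  }, numeric(length(features)))
  matrix(out, nrow = length(features),
         dimnames = list(features, groups))
}

#' Row-wise z-scoring (population standard deviation)
#'
#' Each row is centred to mean 0 and scaled to population (divide-by-n)
#' standard deviation 1, the scaling used for the clustered shape patterns.
#' Constant rows map to all zeros with a warning. Idempotent.
#'
#' @param x Numeric matrix with at least 2 columns.
#' @return The row-scaled matrix.
#' @export
zscoreRows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) .stopf("row scaling needs at least 2 columns")
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  flat <- sdp == 0
  if (any(flat))
    .warnf("%d constant row(s) scaled to zero", sum(flat))
  sdp[flat] <- 1
  out <- (x - mu) / sdp
  out[flat, ] <- 0
  out
}

## squared distances of every row of x to each centre; n x k matrix
.sqDistToCenters <- function(x, centers) {
  k <- nrow(centers)
  vapply(seq_len(k), function(j)
    rowSums((x - matrix(centers[j, ], nrow(x), ncol(x), byrow = TRUE))^2),
    numeric(nrow(x)))
}

## k-means++ style seeding: first centre uniform, then proportional to
## squared distance from the nearest chosen centre.
.kmppIndices <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k == 1L) return(idx)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq.int(2L, k)) {
    if (all(d2 == 0)) {
      idx[j] <- sample(setdiff(seq_len(n), idx[seq_len(j - 1L)]), 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  idx
}

## One Lloyd fit from explicit centres; NULL when stats::kmeans rejects the
## start (duplicate centres, empty clusters, ...).
.lloydFit <- function(x, centers) {
  if (anyDuplicated(centers) > 0L) return(NULL)
  tryCatch(suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 100L,
                  algorithm = "Lloyd")),
    error = function(e) NULL)
}

## Best-of-restarts Lloyd solution. extraCenters: list of centre matrices to
## try in addition to the k-means++ starts (used to inherit the k-1 solution
## when tracing the SSE curve). Always returns a usable model: if every
## Lloyd run fails, the best start is evaluated by nearest-centre assignment.
.kmeansBest <- function(x, k, nInit, extraCenters = list()) {
  n <- nrow(x)
  distinct <- unique(x)
  if (k >= nrow(distinct)) {
    ## every distinct profile its own centroid; SSE is exactly 0
    centers <- distinct[rep(seq_len(nrow(distinct)), length.out = k), ,
                        drop = FALSE]
    assign <- apply(.sqDistToCenters(x, distinct), 1L, which.min)
    return(list(centers = centers, cluster = assign, sse = 0))
  }
  best <- NULL
  starts <- c(extraCenters,
              lapply(seq_len(nInit), function(i)
                x[.kmppIndices(x, k), , drop = FALSE]))
  for (st in starts) {
    fit <- .lloydFit(x, st)
    if (!is.null(fit)) {
      cand <- list(centers = fit$centers, cluster = fit$cluster,
                   sse = sum(fit$withinss))
    } else {
      d2 <- .sqDistToCenters(x, st)
      cl <- apply(d2, 1L, which.min)
      cand <- list(centers = st, cluster = cl,
                   sse = sum(d2[cbind(seq_len(n), cl)]))
    }
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  best
}

#' Fit a K-means co-expression model
#'
#' Best-of-\code{nInit} Lloyd solution from k-means++-style seeded starts;
#' deterministic given the seed. Clustering is performed on the profile
#' matrix exactly as supplied (row-scale beforehand with
#' \code{\link{zscoreRows}} to cluster on shape rather than level).
#'
#' @param profiles Numeric matrix, features x groups.
#' @param k Number of clusters (1 <= k <= number of features).
#' @param seed Integer RNG seed.
#' @param nInit Number of random restarts (default 25).
#' @return A \linkS4class{ClusterModel} (core members unfilled).
#' @export
kmeansCluster <- function(profiles, k, seed, nInit = 25L) {
  profiles <- as.matrix(profiles)
  if (k < 1L) .stopf("k must be >= 1")
  if (k > nrow(profiles))
    .stopf("k = %d exceeds the number of features (%d)", k, nrow(profiles))
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("feature%d", seq_len(nrow(profiles)))
  fit <- .withSeed(seed, .kmeansBest(profiles, as.integer(k), nInit))
  centroids <- as.matrix(fit$centers)
  dimnames(centroids) <- list(NULL, colnames(profiles))
  new("ClusterModel", k = as.integer(k), centroids = centroids,
      assignments = setNames(as.integer(fit$cluster), rownames(profiles)),
      sse = fit$sse, seed = as.numeric(seed), nInit = as.integer(nInit),
      core = list())
}

#' SSE-versus-k curve
#'
#' For each k the best-of-restarts Lloyd solution is computed; in addition
#' to the k-means++ starts, each k inherits the previous k's solution with
#' its worst-fitted point split into a new centre, which makes the returned
#' curve non-increasing in k.
#'
#' @param profiles Numeric matrix, features x groups.
#' @param kMax Largest k (must not exceed the feature count).
#' @param seed Integer RNG seed.
#' @param nInit Restarts per k (default 25).
#' @return data.frame with columns \code{k}, \code{sse}.
#' @export
sseCurve <- function(profiles, kMax, seed, nInit = 25L) {
  profiles <- as.matrix(profiles)
  if (kMax < 1L) .stopf("kMax must be >= 1")
  if (kMax > nrow(profiles))
    .stopf("kMax = %d exceeds the number of features (%d)", kMax,
           nrow(profiles))
  .withSeed(seed, {
    sse <- numeric(kMax)
    prev <- NULL
    for (k in seq_len(kMax)) {
      extra <- list()
      if (!is.null(prev) && prev$sse > 0) {
        d2 <- .sqDistToCenters(profiles, prev$centers)
        ownD <- d2[cbind(seq_len(nrow(profiles)), prev$cluster)]
        far <- which.max(ownD)
        extra <- list(rbind(prev$centers, profiles[far, ]))
      }
      fit <- .kmeansBest(profiles, k, nInit, extraCenters = extra)
      if (!is.null(prev) && fit$sse > prev$sse) fit <- prev  # safety net
      sse[k] <- fit$sse
      prev <- fit
    }
    data.frame(k = seq_len(kMax), sse = sse)
  })
}

#' Choose k at the elbow of the SSE curve
#'
#' Picks the k maximizing the discrete second difference
#' \code{sse(k-1) - 2 sse(k) + sse(k+1)} (ties resolved to the smallest k).
#' A strictly linear curve has no elbow; the smallest interior k is returned
#' with a warning. The full diagnostic table is attached so a user can
#' override the automatic choice.
#'
#' @param curve data.frame from \code{\link{sseCurve}} with at least 3 rows.
#' @return List with elements \code{k} (the chosen cluster count) and
#'   \code{diagnostics} (data.frame of k, sse, second_diff).
#' @export
chooseKElbow <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("k", "sse") %in% names(curve)))
  if (nrow(curve) < 3L) .stopf("the SSE curve needs at least 3 points")
  curve <- curve[order(curve$k), , drop = FALSE]
  s <- curve$sse
  d2 <- rep(NA_real_, nrow(curve))
  inner <- seq.int(2L, nrow(curve) - 1L)
  d2[inner] <- s[inner - 1L] - 2 * s[inner] + s[inner + 1L]
  if (diff(range(d2[inner])) < 1e-12) {
    .warnf("no clear elbow: the SSE curve is linear in k")
    kBest <- curve$k[inner[1L]]
  } else {
    kBest <- curve$k[inner[which.max(d2[inner])]]
  }
  list(k = kBest,
       diagnostics = data.frame(k = curve$k, sse = s, second_diff = d2))
}

#' Extract correlation-filtered core members
#'
#' Per cluster, the core is the set of members whose Pearson correlation
#' between their profile row and the cluster centroid (over the group axis)
#' strictly exceeds \code{rThreshold}. Members with a constant profile
#' (undefined correlation) are excluded with a warning.
#'
#' @param model A \linkS4class{ClusterModel} fitted on these profiles.
#' @param profiles The feature-by-group matrix the model was fitted on.
#' @param rThreshold Correlation threshold (default 0.8, strict).
#' @return The \linkS4class{ClusterModel} with its \code{core} slot filled.
#' @export
extractCore <- function(model, profiles, rThreshold = 0.8) {
  stopifnot(is(model, "ClusterModel"))
  profiles <- as.matrix(profiles)
  if (!all(names(model@assignments) %in% rownames(profiles)))
    .stopf("profiles do not cover the model's features")
  core <- vector("list", model@k)
  nFlat <- 0L
  for (cl in seq_len(model@k)) {
    members <- names(model@assignments)[model@assignments == cl]
    centroid <- model@centroids[cl, ]
    rows <- lapply(members, function(f) {
      prof <- profiles[f, ]
      if (stats::sd(prof) == 0 || stats::sd(centroid) == 0) {
        nFlat <<- nFlat + 1L
        return(NULL)
      }
      r <- stats::cor(prof, centroid)
      if (r > rThreshold) data.frame(feature = f, r = r,
                                     stringsAsFactors = FALSE)
      else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    core[[cl]] <- if (length(rows) > 0L) do.call(rbind, rows)
      else data.frame(feature = character(0L), r = numeric(0L))
    rownames(core[[cl]]) <- NULL
  }
  if (nFlat > 0L)
    .warnf("%d member(s) with undefined centroid correlation excluded from the core",
           nFlat)
  model@core <- core
  model
}

#' Heatmap export panels for the core members
#'
#' Three aligned tables restricted to core members, ordered by cluster and,
#' within a cluster, by average-linkage hierarchical leaf order on Euclidean
#' distances of the row-scaled mean profiles: row-scaled group-mean
#' expression, row-scaled per-sample expression, and per-comparison log2
#' fold changes taken from the DE tables.
#'
#' @param m The log2-scale \linkS4class{ExpressionMatrix}.
#' @param design The \linkS4class{SampleDesign}.
#' @param model A \linkS4class{ClusterModel} with core members extracted.
#' @param deTables Named list of called \linkS4class{DEResult} tables.
#' @return List with elements \code{features}, \code{cluster},
#'   \code{mean_scaled}, \code{sample_scaled}, \code{fold_change}.
#' @export
heatmapExport <- function(m, design, model, deTables) {
  stopifnot(is(m, "ExpressionMatrix"), is(model, "ClusterModel"))
  if (length(model@core) == 0L)
    .stopf("extract core members before exporting heatmap panels")
  feats <- character(0L); clusters <- integer(0L)
  for (cl in seq_len(model@k)) {
    members <- model@core[[cl]]$feature
    if (length(members) > 1L) {
      prof <- zscoreRows(groupMeanProfile(m, design, members))
      ord <- stats::hclust(stats::dist(prof), method = "average")$order
      members <- members[ord]
    }
    feats <- c(feats, members)
    clusters <- c(clusters, rep(cl, length(members)))
  }
  if (length(feats) == 0L) {
    empty <- matrix(numeric(0L), 0L, 0L)
    return(list(features = character(0L), cluster = integer(0L),
                mean_scaled = empty, sample_scaled = empty,
                fold_change = empty))
  }
  meanScaled <- zscoreRows(groupMeanProfile(m, design, feats))
  sampleScaled <- zscoreRows(exprValues(m)[feats, , drop = FALSE])
  fc <- vapply(deTables, function(tab)
    setNames(tab$log2fc, rownames(tab))[feats], numeric(length(feats)))
  fc <- matrix(fc, nrow = length(feats),
               dimnames = list(feats, names(deTables)))
  list(features = feats, cluster = clusters, mean_scaled = meanScaled,
       sample_scaled = sampleScaled, fold_change = fc)
}

#' Sample scores on the first two principal components
#'
#' Feature-centred covariance PCA via singular value decomposition. Sign
#' convention: within each component the largest-magnitude feature loading
#' is made positive.
#'
#' @param m An \linkS4class{ExpressionMatrix} with at least 2 samples.
#' @return List with \code{scores} (samples x 2) and \code{explained}
#'   (fractions of total variance for PC1 and PC2).
#' @export
pcaScores <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (ncol(m) < 2L) .stopf("PCA needs at least 2 samples")
  x <- t(exprValues(m))                       # samples x features
  x <- sweep(x, 2L, colMeans(x), "-")
  sv <- svd(x)
  ncomp <- min(2L, length(sv$d))
  scores <- matrix(0, nrow(x), 2L,
                   dimnames = list(rownames(x), c("PC1", "PC2")))
  for (j in seq_len(ncomp)) {
    load <- sv$v[, j]
    flip <- if (load[which.max(abs(load))] < 0) -1 else 1
    scores[, j] <- flip * sv$u[, j] * sv$d[j]
  }
  tot <- sum(sv$d^2)
  explained <- c(PC1 = 0, PC2 = 0)
  if (tot > 0)
    explained[seq_len(ncomp)] <- sv$d[seq_len(ncomp)]^2 / tot
  list(scores = scores, explained = explained)
}
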