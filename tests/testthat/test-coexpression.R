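test_that("feature selection is the union of significant calls", {
  cmp <- Comparison("A", "B")
  mk <- function(features, status) {
    df <- S4Vectors::DataFrame(mean_a = 0, mean_b = 0, log2fc = 0,
                               signed_fc = 1, t_mod = 0, df_total = 1,
                               p_raw = 1, p_adj = 1, status = status,
                               row.names = features)
    res <- new("DEResult", df)
    S4Vectors::metadata(res)$comparison <- cmp
    res
  }
  tabs <- list(mk(c("m1", "m2", "m3"), c("up", "ns", "ns")),
               mk(c("m1", "m2", "m3"), c("ns", "down", "ns")))
  expect_identical(selectClusteringFeatures(tabs), c("m1", "m2"))
  expect_identical(selectClusteringFeatures(list(mk("m1", "ns"))),
                   character(0L))
  ## equals brute-force set union
  expect_setequal(selectClusteringFeatures(tabs),
                  union(c("m1"), c("m2")))
})

test_that("group-mean profiles equal brute-force means", {
  sim <- cachedSim(1L)
  feats <- featureIds(sim$mirna)[1:5]
  prof <- groupMeanProfile(sim$mirna, sim$design, feats)
  v <- exprValues(sim$mirna)
  for (g in groupOrder(sim$design)) {
    cols <- samplesInGroup(sim$design, g)
    expect_equal(prof[, g], rowMeans(v[feats, cols]), tolerance = 1e-12)
  }
  expect_error(groupMeanProfile(sim$mirna, sim$design, "nope"), "unknown")

  ## single-sample groups: means are the values themselves
  m <- toyMatrix(3L, 2L, seed = 2L)
  d <- SampleDesign(setNames(c("A", "B"), sampleIds(m)))
  expect_equal(unname(groupMeanProfile(m, d)), unname(exprValues(m)))
})

test_that("row z-scoring uses the population sd and is idempotent", {
  z <- zscoreRows(matrix(c(1, 2, 3), 1L, 3L))
  expect_equal(unname(z[1L, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_warning(zc <- zscoreRows(matrix(5, 2L, 4L)), "constant")
  expect_true(all(zc == 0))
  x <- matrix(rnorm(30), 5L)
  expect_equal(zscoreRows(zscoreRows(x)), zscoreRows(x), tolerance = 1e-9)
})

test_that("SSE curve hits its closed-form endpoints and never increases", {
  set.seed(12)
  prof <- matrix(rnorm(60), 10L, 6L,
                 dimnames = list(sprintf("f%02d", 1:10), NULL))
  curve <- sseCurve(prof, kMax = 10L, seed = 3L, nInit = 10L)
  expect_equal(curve$sse[1L],
               sum(sweep(prof, 2L, colMeans(prof))^2), tolerance = 1e-9)
  expect_equal(curve$sse[10L], 0)
  expect_true(all(diff(curve$sse) <= 1e-9))
  expect_error(sseCurve(prof, 0L, seed = 1L), "kMax")
})

test_that("the elbow finds a constructed breakpoint and flags linear curves", {
  curve <- data.frame(k = 1:6, sse = c(100, 20, 18, 16, 14, 12))
  pick <- chooseKElbow(curve)
  expect_equal(pick$k, 2L)
  expect_equal(pick$diagnostics$second_diff[2L], 100 - 40 + 18)

  linear <- data.frame(k = 1:5, sse = c(50, 40, 30, 20, 10))
  expect_warning(pickLin <- chooseKElbow(linear), "no clear elbow")
  expect_equal(pickLin$k, 2L)
  expect_error(chooseKElbow(data.frame(k = 1:2, sse = c(2, 1))), "3 points")
})

test_that("k-means is deterministic under a fixed seed with exact bookkeeping", {
  set.seed(5)
  prof <- rbind(matrix(rnorm(24, 0), 4L, 6L), matrix(rnorm(36, 5), 6L, 6L))
  rownames(prof) <- sprintf("f%02d", 1:10)
  m1 <- kmeansCluster(prof, 2L, seed = 7L)
  m2 <- kmeansCluster(prof, 2L, seed = 7L)
  expect_identical(clusterAssignments(m1), clusterAssignments(m2))
  expect_equal(clusterSse(m1), clusterSse(m2))
  ## stored SSE equals recomputation from assignments and centroids
  recomputed <- sum(vapply(seq_len(nrow(prof)), function(i)
    sum((prof[i, ] - clusterCentroids(m1)[clusterAssignments(m1)[i], ])^2),
    numeric(1L)))
  expect_equal(clusterSse(m1), recomputed, tolerance = 1e-9)

  k1 <- kmeansCluster(prof, 1L, seed = 7L)
  expect_equal(unname(clusterCentroids(k1)[1L, ]), unname(colMeans(prof)),
               tolerance = 1e-12)
  expect_error(kmeansCluster(prof, 11L, seed = 1L), "exceeds")
})

test_that("core extraction keeps only members correlating above the threshold", {
  centroidUp <- c(0, 1, 2, 3, 4, 5)
  prof <- rbind(up1 = centroidUp, up2 = centroidUp + 0.01,
                anti = rev(centroidUp), flat = rep(1, 6L))
  model <- new("ClusterModel", k = 1L,
               centroids = matrix(centroidUp, 1L),
               assignments = setNames(rep(1L, 4L), rownames(prof)),
               sse = 0, seed = 1, nInit = 1L, core = list())
  expect_warning(model <- extractCore(model, prof, 0.8), "undefined")
  core <- coreMembers(model)[[1L]]
  expect_setequal(core$feature, c("up1", "up2"))   # anti has r = -1
  expect_true(all(core$r > 0.8))

  ## brute-force correlation check on a small fixture
  set.seed(9)
  prof2 <- matrix(rnorm(60), 10L, 6L,
                  dimnames = list(sprintf("f%02d", 1:10), NULL))
  fit <- kmeansCluster(prof2, 2L, seed = 4L)
  fit <- extractCore(fit, prof2, 0.5)
  for (cl in 1:2) {
    members <- names(clusterAssignments(fit))[clusterAssignments(fit) == cl]
    expected <- members[vapply(members, function(f)
      cor(prof2[f, ], clusterCentroids(fit)[cl, ]) > 0.5, logical(1L))]
    expect_setequal(coreMembers(fit)[[cl]]$feature, expected)
  }

  ## core membership is invariant to row scaling (Pearson affine invariance)
  fitScaled <- extractCore(fit, 3 * prof2 + 2, 0.5)
  for (cl in 1:2)
    expect_setequal(coreMembers(fitScaled)[[cl]]$feature,
                    coreMembers(fit)[[cl]]$feature)
})

test_that("two planted archetypes are recovered with the elbow at k = 2", {
  sim <- cachedSim(8L, small = FALSE)
  deTables <- lapply(defaultComparisons(), function(cmp)
    callDifferential(moderatedTTest(sim$mirna, sim$design, cmp)))
  feats <- selectClusteringFeatures(deTables)
  prof <- zscoreRows(groupMeanProfile(sim$mirna, sim$design, feats))
  curve <- sseCurve(prof, 8L, seed = 2L)
  expect_equal(chooseKElbow(curve)$k, 2L)
  model <- kmeansCluster(prof, 2L, seed = 2L)
  truthLab <- clusterLabels(sim$truth)
  common <- intersect(names(clusterAssignments(model)), names(truthLab))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(clusterAssignments(model)[common],
                                   truthLab[common])
  expect_gte(ari, 0.9)
})

test_that("heatmap panels align core members with their DE fold changes", {
  sim <- cachedSim(1L)
  cmp <- defaultComparisons()[[7L]]
  res <- callDifferential(moderatedTTest(sim$mirna, sim$design, cmp))
  feats <- selectClusteringFeatures(list(res))
  prof <- zscoreRows(groupMeanProfile(sim$mirna, sim$design, feats))
  model <- extractCore(kmeansCluster(prof, 2L, seed = 1L), prof)
  hm <- heatmapExport(sim$mirna, sim$design, model,
                      setNames(list(res), cmp@name))
  expect_equal(length(hm$features), length(hm$cluster))
  expect_identical(rownames(hm$mean_scaled), hm$features)
  expect_identical(rownames(hm$sample_scaled), hm$features)
  fcRef <- setNames(res$log2fc, rownames(res))[hm$features]
  expect_equal(unname(hm$fold_change[, cmp@name]), unname(fcRef))
  ## rows are grouped by cluster
  expect_true(!is.unsorted(hm$cluster))
})

test_that("PCA scores match an eigendecomposition oracle with consistent signs", {
  m <- toyMatrix(30L, 8L, seed = 6L)
  sc <- pcaScores(m)
  expect_equal(dim(sc$scores), c(8L, 2L))
  expect_lte(sum(sc$explained), 1 + 1e-12)

  x <- t(exprValues(m)); x <- sweep(x, 2L, colMeans(x))
  eig <- eigen(x %*% t(x), symmetric = TRUE)
  for (j in 1:2) {
    ref <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_equal(abs(unname(sc$scores[, j])), abs(ref), tolerance = 1e-8)
    expect_equal(sc$explained[[j]], eig$values[j] / sum(eig$values),
                 tolerance = 1e-8)
  }

  ## duplicated samples get identical scores
  v <- exprValues(m); v[, 2L] <- v[, 1L]
  sc2 <- pcaScores(ExpressionMatrix(v, "log2"))
  expect_equal(sc2$scores[1L, ], sc2$scores[2L, ], tolerance = 1e-9)
})
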