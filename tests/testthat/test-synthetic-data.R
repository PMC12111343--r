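test_that("the generator honours the dimensional contract at defaults", {
  sim <- cachedSim(1L, small = FALSE)
  expect_equal(dim(exprValues(sim$mirna)), c(700L, 18L))
  expect_equal(dim(exprValues(sim$mrna)), c(5000L, 18L))
  expect_identical(exprScale(sim$mirna), "log2")
  expect_length(assignments(sim$design), 18L)
  expect_true(all(table(assignments(sim$design)) == 3L))
  expect_length(plantedDeSets(sim$truth), 7L)
  expect_length(clusterLabels(sim$truth), 60L)
  expect_equal(nrow(plantedEdges(sim$truth)), 300L)
})

test_that("same seed reproduces bit-identical data; different seeds differ", {
  a <- simulateDataset(smallParams(9L))
  b <- simulateDataset(smallParams(9L))
  c <- simulateDataset(smallParams(10L))
  expect_identical(exprValues(a$mirna), exprValues(b$mirna))
  expect_identical(exprValues(a$mrna), exprValues(b$mrna))
  expect_identical(targetRecords(a$targets), targetRecords(b$targets))
  expect_identical(plantedDeSets(a$truth), plantedDeSets(b$truth))
  expect_false(identical(exprValues(a$mirna), exprValues(c$mirna)))
})

test_that("planted repressive edges obey the opposite-sign law everywhere", {
  sim <- cachedSim(2L)
  truth <- sim$truth
  edges <- plantedEdges(truth)
  for (cmpName in names(plantedDeSets(truth))) {
    fc <- plantedDeSets(truth)[[cmpName]]
    onEdge <- edges$mirna %in% names(fc)
    if (!any(onEdge)) next
    prodSign <- sign(fc[edges$mirna[onEdge]]) * sign(fc[edges$gene[onEdge]])
    expect_true(all(prodSign == -1),
                label = sprintf("sign law in %s", cmpName))
  }
})

test_that("at zero noise the realized group-mean differences equal the planted log2FC", {
  params <- SimulationParams(nMirna = 60L, nMrna = 150L,
                             nDeMirnaPerComparison = 5L,
                             targetsPerDeMirna = 2L, noiseSd = 0,
                             seed = 4L)
  sim <- simulateDataset(params)
  cmp <- defaultComparisons()[[7L]]
  prof <- groupMeanProfile(sim$mirna, sim$design)
  profG <- groupMeanProfile(sim$mrna, sim$design)
  planted <- plantedDeSets(sim$truth)[[cmp@name]]
  for (f in names(planted)) {
    p <- if (grepl("^miR", f)) prof else profG
    expect_equal(unname(p[f, cmp@groupA] - p[f, cmp@groupB]),
                 unname(planted[[f]]), tolerance = 1e-9)
  }
})

test_that("a null generator plants nothing and downstream calls are near-silent", {
  params <- SimulationParams(nMirna = 200L, nMrna = 300L,
                             nDeMirnaPerComparison = 0L, seed = 5L)
  sim <- simulateDataset(params)
  expect_true(all(lengths(plantedDeSets(sim$truth)) == 0L))
  expect_equal(nrow(plantedEdges(sim$truth)), 0L)
  cmp <- defaultComparisons()[[7L]]
  res <- callDifferential(moderatedTTest(sim$mirna, sim$design, cmp))
  expect_lte(sum(deCounts(res)), 0.05 * 200)
})

test_that("planted edges carry at least the required source support", {
  sim <- cachedSim(3L)
  params <- smallParams(3L)
  rec <- targetRecords(sim$targets)
  edges <- plantedEdges(sim$truth)
  key <- paste(rec$mirna, rec$gene)
  for (e in seq_len(nrow(edges))) {
    nSrc <- length(unique(rec$source[key == paste(edges$mirna[e],
                                                  edges$gene[e])]))
    expect_gte(nSrc, params@minPlantedSources)
  }
  ## decoys and under-supported edges exist (a false-positive surface)
  expect_gt(sum(!key %in% paste(edges$mirna, edges$gene)), 0L)
})

test_that("truth serialization round-trips losslessly", {
  sim <- cachedSim(2L)
  path <- withr::local_tempfile(fileext = ".json")
  writeTruth(sim$truth, path)
  back <- readTruth(path)
  expect_equal(plantedDeSets(back), plantedDeSets(sim$truth))
  expect_equal(plantedEdges(back), plantedEdges(sim$truth))
  expect_equal(plantedPairs(back), plantedPairs(sim$truth))
  expect_identical(clusterLabels(back), clusterLabels(sim$truth))
  expect_identical(enrichedTerms(back), enrichedTerms(sim$truth))

  ## empty truth is a valid file with zero rows
  params <- SimulationParams(nMirna = 50L, nMrna = 100L,
                             nDeMirnaPerComparison = 0L, seed = 1L)
  empty <- simulateDataset(params)$truth
  writeTruth(empty, path)
  back2 <- readTruth(path)
  expect_equal(nrow(plantedEdges(back2)), 0L)
})

test_that("invalid simulation parameters fail before any sampling", {
  expect_error(SimulationParams(repsPerGroup = 1L), "repsPerGroup")
  expect_error(SimulationParams(effectLow = 0.5), "effectLow")
  expect_error(SimulationParams(minPlantedSources = 6L, nSources = 5L),
               "minPlantedSources")
})
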