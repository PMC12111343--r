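test_that("quantile normalization matches the hand-computed reference", {
  ## columns (1,2) and (3,4): mean order statistics are (1+3)/2 = 2 and
  ## (2+4)/2 = 3, so both columns map onto (2, 3) at their rank positions
  v <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  out <- exprValues(quantileNormalize(ExpressionMatrix(v, "log2")))
  expect_equal(unname(out[, 1L]), c(2, 3))
  expect_equal(unname(out[, 2L]), c(2, 3))

  ## tied values share the mean of the reference values at their positions
  vt <- matrix(c(1, 1, 2, 4), 2, 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  outT <- exprValues(quantileNormalize(ExpressionMatrix(vt, "log2")))
  expect_equal(unname(outT[, 1L]), c(2, 2))   # mean of references (1.5, 2.5)
  expect_equal(unname(outT[, 2L]), c(1.5, 2.5))
})

test_that("quantile normalization equalizes columns, fixes identical input, and is idempotent", {
  m <- toyMatrix(50L, 6L, seed = 2L)
  q1 <- quantileNormalize(m)
  means <- colMeans(exprValues(q1))
  expect_lt(diff(range(means)), 1e-9)
  q2 <- quantileNormalize(q1)
  expect_lt(max(abs(exprValues(q2) - exprValues(q1))), 1e-9)

  same <- ExpressionMatrix(matrix(rep(c(5, 6, 7), 3), 3, 3,
                                  dimnames = list(letters[1:3], LETTERS[1:3])),
                           "log2")
  expect_equal(exprValues(quantileNormalize(same)), exprValues(same))

  single <- toyMatrix(5L, 1L)
  expect_error(quantileNormalize(single), "2 samples")
})

test_that("median polish: single probes pass through, additive matrices are exact", {
  m <- toyMatrix(4L, 5L, seed = 3L)
  probeMap <- setNames(featureIds(m), featureIds(m))
  out <- medianPolishSummarize(m, probeMap)
  expect_equal(exprValues(out)[featureIds(m), ], exprValues(m))

  ## purely additive probe matrix: recovered column effects are exact
  rowEff <- c(0, 0.5, -0.3, 1.2, 0.1)
  colEff <- c(7, 8, 6.5, 7.7)
  probes <- outer(rowEff, colEff, "+")
  dimnames(probes) <- list(sprintf("p%d", 1:5), sprintf("s%d", 1:4))
  pm <- ExpressionMatrix(probes, "log2")
  res <- medianPolishSummarize(pm, setNames(rep("featA", 5L),
                                            sprintf("p%d", 1:5)))
  got <- exprValues(res)["featA", ]
  ## column effects recovered up to the overall shift convention
  expect_lt(max(abs(diff(got) - diff(colEff))), 1e-6)
})

test_that("median polish agrees with an independent sweep implementation", {
  ## reference: alternate row/column median sweeps written out longhand
  referencePolish <- function(x, maxIter = 10L, eps = 1e-6) {
    overall <- 0; rowE <- rep(0, nrow(x)); colE <- rep(0, ncol(x))
    r <- x
    for (i in seq_len(maxIter)) {
      rm <- apply(r, 1L, median)
      r <- r - rm; rowE <- rowE + rm
      dc <- median(rowE); rowE <- rowE - dc; overall <- overall + dc
      cm <- apply(r, 2L, median)
      r <- sweep(r, 2L, cm); colE <- colE + cm
      dr <- median(colE); colE <- colE - dr; overall <- overall + dr
      if (max(abs(c(rm, cm))) < eps) break
    }
    overall + colE
  }
  set.seed(8)
  probes <- matrix(rnorm(20, 7), 5L, 4L,
                   dimnames = list(sprintf("p%d", 1:5), sprintf("s%d", 1:4)))
  pm <- ExpressionMatrix(probes, "log2")
  res <- medianPolishSummarize(pm, setNames(rep("f", 5L), rownames(probes)))
  expect_equal(unname(exprValues(res)["f", ]), unname(referencePolish(probes)),
               tolerance = 1e-6)
})

test_that("variance filtering drops the flattest rows and preserves order", {
  m <- toyMatrix(10L, 6L, seed = 4L)
  v <- exprValues(m); v[3L, ] <- 5
  m <- ExpressionMatrix(v, "log2")
  expect_identical(exprValues(filterLowVariance(m, 0)), exprValues(m))
  f <- filterLowVariance(m, 0.1)
  expect_false("miR-003" %in% featureIds(f))
  expect_identical(featureIds(f), setdiff(featureIds(m), "miR-003"))
  expect_equal(exprValues(f), exprValues(m)[featureIds(f), ])
  expect_error(filterLowVariance(m, 1), "quantileCut")

  ## survivor count tracks the variance quantile within tie tolerance
  m2 <- toyMatrix(40L, 6L, seed = 5L)
  kept <- nrow(filterLowVariance(m2, 0.5))
  vars <- sort(apply(exprValues(m2), 1L, var))
  expected <- sum(vars >= quantile(vars, 0.5))
  expect_equal(kept, expected)
  expect_lte(abs(kept - ceiling(40 / 2)), 1L)
})

test_that("log2 transform and background floor guard zeros and scale tags", {
  lin <- ExpressionMatrix(matrix(c(0, 3, 7, 15), 2, 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))),
                          "linear")
  lg <- log2Transform(lin)
  expect_identical(exprScale(lg), "log2")
  expect_equal(exprValues(lg)[1L, 1L], 0)
  expect_equal(exprValues(lg)[2L, 2L], 4)
  expect_error(log2Transform(lg), "linear-scale")

  bg <- floorShiftBackground(lin, percentile = 0)
  expect_true(all(exprValues(bg) >= 0))
})
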