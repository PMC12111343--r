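test_that("equal variances collapse the prior to full shrinkage", {
  pr <- fitVariancePrior(rep(0.04, 50L), dG = 4)
  expect_true(is.infinite(pr@d0))
  expect_gt(pr@s0Sq, 0)

  ## two spread-out variances still give a finite positive d0
  pr2 <- fitVariancePrior(c(0.001, 4), dG = 4)
  expect_true(is.finite(pr2@d0) && pr2@d0 > 0)

  expect_error(fitVariancePrior(0.1, dG = 4), "at least 2")
  expect_warning(fitVariancePrior(c(0, 0.1, 0.2, 0.4), dG = 4),
                 "non-positive")
})

test_that("the prior fit recovers the generating hyper-parameters", {
  ## variances simulated from the moderated-t model itself:
  ## tau^2 ~ scaled-inv-chisq(d0 = 4, s0^2 = 0.0625), s^2 | tau^2 on 4 df
  for (s in 1:3) {
    set.seed(s)
    tau2 <- 4 * 0.0625 / rchisq(10000L, 4)
    s2 <- tau2 * rchisq(10000L, 4) / 4
    pr <- fitVariancePrior(s2, dG = 4)
    expect_gt(pr@d0, 3); expect_lt(pr@d0, 5.5)
    expect_lt(abs(pr@s0Sq / 0.0625 - 1), 0.15)
  }
})

test_that("the prior fit matches limma's F-distribution fit", {
  set.seed(21)
  tau2 <- 4 * 0.05 / rchisq(3000L, 4)
  s2 <- tau2 * rchisq(3000L, 4) / 4
  pr <- fitVariancePrior(s2, dG = 4)
  fd <- limma::fitFDist(s2, df1 = 4)
  expect_equal(pr@d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr@s0Sq, fd$scale, tolerance = 1e-6)
})

test_that("d0 = 0 reduces to the ordinary pooled two-sample t-test", {
  design <- twoGroupDesign(3L)
  prior <- VariancePrior(d0 = 0, s0Sq = 1)
  cmp <- Comparison("A", "B")
  set.seed(31)
  for (rep in 1:50) {
    m <- toyMatrix(20L, 6L, seed = rep + 100L)
    res <- moderatedTTest(m, design, cmp, prior)
    v <- exprValues(m)
    for (f in sample(featureIds(m), 4L)) {
      ref <- pooledT(v[f, 1:3], v[f, 4:6])
      expect_equal(unname(res[f, "t_mod"]), ref$t, tolerance = 1e-10)
      expect_equal(unname(res[f, "p_raw"]), ref$p, tolerance = 1e-10)
      expect_equal(unname(res[f, "df_total"]), ref$df)
    }
  }
})

test_that("moderated statistics equal direct formula evaluation with a fixed prior", {
  design <- twoGroupDesign(3L)
  cmp <- Comparison("A", "B")
  prior <- VariancePrior(d0 = 4, s0Sq = 0.05)
  m <- toyMatrix(200L, 6L, seed = 77L)
  res <- moderatedTTest(m, design, cmp, prior)
  v <- exprValues(m)
  for (f in featureIds(m)) {
    xA <- v[f, 1:3]; xB <- v[f, 4:6]
    sg2 <- (2 * var(xA) + 2 * var(xB)) / 4
    st2 <- (4 * 0.05 + 4 * sg2) / 8
    tRef <- (mean(xA) - mean(xB)) / sqrt(st2 * (2 / 3))
    expect_equal(unname(res[f, "t_mod"]), tRef, tolerance = 1e-12)
    expect_equal(unname(res[f, "df_total"]), 8)
    expect_equal(unname(res[f, "p_raw"]), 2 * pt(-abs(tRef), 8), tolerance = 1e-12)
  }
  ## moderation shrinks: posterior variance strictly between prior and sample
  sg2 <- apply(v, 1L, function(x) (2 * var(x[1:3]) + 2 * var(x[4:6])) / 4)
  st2 <- (4 * 0.05 + 4 * sg2) / 8
  differ <- abs(sg2 - 0.05) > 1e-12
  expect_true(all(st2[differ] > pmin(sg2, 0.05)[differ] &
                    st2[differ] < pmax(sg2, 0.05)[differ]))
})

test_that("moderated t agrees with limma's eBayes pipeline", {
  design <- twoGroupDesign(3L)
  cmp <- Comparison("A", "B")
  m <- toyMatrix(300L, 6L, seed = 55L)
  res <- moderatedTTest(m, design, cmp, "estimate")
  dm <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(exprValues(m), dm))
  expect_equal(unname(res$t_mod), unname(fit$t[, 2L]), tolerance = 1e-8)
  expect_equal(unname(res$p_raw), unname(fit$p.value[, 2L]), tolerance = 1e-8)
})

test_that("degenerate features get t = 0, p = 1 instead of NaN", {
  v <- matrix(7, 2, 6, dimnames = list(c("flat", "flat2"),
                                       sprintf("s%02d", 1:6)))
  m <- ExpressionMatrix(v, "log2")
  design <- twoGroupDesign(3L)
  prior <- VariancePrior(d0 = 0, s0Sq = 1)
  res <- moderatedTTest(m, design, Comparison("A", "B"), prior)
  expect_equal(unname(res$t_mod), c(0, 0))
  expect_equal(unname(res$p_raw), c(1, 1))
})

test_that("group errors are caught before any computation", {
  m <- toyMatrix(5L, 6L, seed = 1L)
  design <- twoGroupDesign(3L)
  expect_error(moderatedTTest(m, design, Comparison("A", "Z")), "missing")
  d2 <- SampleDesign(setNames(c("A", "A", "A", "A", "A", "B"),
                              sprintf("s%02d", 1:6)))
  expect_error(moderatedTTest(m, d2, Comparison("A", "B")), "at least 2")
})

test_that("BH adjustment matches the step-up definition, including ties", {
  expect_equal(benjaminiHochberg(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(benjaminiHochberg(rep(0.2, 5L)), rep(0.2, 5L))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:200) {
    p <- round(runif(sample(1:8, 1L)), 3L)
    adj <- benjaminiHochberg(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-12)
    ## monotone in p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("the compound cut-off gates on fold change, raw p and FDR together", {
  cmp <- Comparison("A", "B")
  mk <- function(l2fc, praw, padj) {
    df <- S4Vectors::DataFrame(
      mean_a = l2fc, mean_b = 0, log2fc = l2fc,
      signed_fc = ifelse(l2fc >= 0, 2^l2fc, -2^(-l2fc)),
      t_mod = 1, df_total = 8, p_raw = praw, p_adj = padj,
      status = rep("ns", length(l2fc)),
      row.names = sprintf("f%d", seq_along(l2fc)))
    res <- new("DEResult", df)
    S4Vectors::metadata(res)$comparison <- cmp
    res
  }
  res <- callDifferential(mk(c(2, 0.9, -1.7, 1.5, 1.5),
                             c(0.001, 1e-6, 0.002, 0.2, 0.01),
                             c(0.01, 1e-5, 0.05, 0.5, 0.35)))
  expect_equal(unname(res$status), c("up", "ns", "down", "ns", "ns"))
  expect_equal(deCounts(res), c(down = 1L, up = 1L))
  expect_error(callDifferential(mk(1, 0.5, 0.5), fcThreshold = 0),
               "positive")
  ## counts are invariant to feature order
  res2 <- callDifferential(mk(c(1.5, -1.7, 1.5, 0.9, 2),
                              c(0.01, 0.002, 0.2, 1e-6, 0.001),
                              c(0.35, 0.05, 0.5, 1e-5, 0.01)))
  expect_equal(deCounts(res2), deCounts(res))
})

test_that("a null simulation stays below the nominal type-I budget", {
  calls <- vapply(1:10, function(s) {
    params <- SimulationParams(nMirna = 1000L, nMrna = 100L,
                               nDeMirnaPerComparison = 0L, seed = s)
    sim <- simulateDataset(params)
    res <- callDifferential(moderatedTTest(sim$mirna, sim$design,
                                           defaultComparisons()[[7L]]))
    sum(deCounts(res))
  }, numeric(1L))
  expect_lte(mean(calls), 0.05 * 1000)
})

test_that("ddCt fold changes and Student's t agree with the textbook formulas", {
  design <- twoGroupDesign(3L, c("ref", "cmp"))
  ct <- matrix(c(20, 20, 20, 20, 20, 20,        # reference gene
                 25, 25, 25, 24, 24, 24),       # target: ddCt = -1
               nrow = 2L, byrow = TRUE,
               dimnames = list(c("RNU1A1", "miR-X"), sprintf("s%02d", 1:6)))
  tab <- CtTable(ct, "RNU1A1", design)
  res <- qpcrDdct(tab, refGroup = "ref", cmpGroup = "cmp")
  expect_equal(res$ddct, -1)
  expect_equal(res$fold_change, 2)

  ## identical groups: fold 1, p 1
  ct2 <- ct; ct2["miR-X", ] <- 25
  res2 <- qpcrDdct(CtTable(ct2, "RNU1A1", design), "ref", "cmp")
  expect_equal(res2$fold_change, 1)
  expect_equal(res2$p, 1)

  ## random fixture vs independent pooled-t oracle
  set.seed(17)
  ct3 <- ct; ct3["miR-X", ] <- rnorm(6L, 24, 0.4)
  res3 <- qpcrDdct(CtTable(ct3, "RNU1A1", design), "ref", "cmp")
  dct <- ct3["miR-X", ] - ct3["RNU1A1", ]
  ref <- pooledT(dct[4:6], dct[1:3])
  expect_equal(res3$p, ref$p, tolerance = 1e-10)
  expect_equal(res3$fold_change, 2^(-(mean(dct[4:6]) - mean(dct[1:3]))),
               tolerance = 1e-12)
})

test_that("volcano export is a lossless projection of the DE table", {
  sim <- cachedSim(1L)
  res <- callDifferential(moderatedTTest(sim$mirna, sim$design,
                                         defaultComparisons()[[7L]]))
  vt <- volcanoTable(res)
  expect_equal(nrow(vt), nrow(res))
  expect_identical(vt$feature, rownames(res))
  expect_equal(vt$log2fc, unname(res$log2fc))
  expect_equal(vt$neg_log10_p_raw, unname(-log10(pmax(res$p_raw, 1e-300))),
               tolerance = 1e-9)
  ## signed fold change convention: |signed_fc| >= 1 with the sign of log2fc
  expect_true(all(abs(res$signed_fc) >= 1))
  expect_true(all(sign(res$signed_fc) == ifelse(res$log2fc >= 0, 1, -1)))
})
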