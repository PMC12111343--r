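## Shared in-code fixtures. Everything is generated programmatically; small
## simulations are cached per seed so several test files can reuse them.

toyMatrix <- function(nFeat = 10L, nSamp = 6L, seed = 1L, scale = "log2") {
  set.seed(seed)
  m <- matrix(rnorm(nFeat * nSamp, mean = 7, sd = 1), nFeat, nSamp,
              dimnames = list(sprintf("miR-%03d", seq_len(nFeat)),
                              sprintf("s%02d", seq_len(nSamp))))
  ExpressionMatrix(m, scale)
}

twoGroupDesign <- function(nPer = 3L, groups = c("A", "B")) {
  ids <- sprintf("s%02d", seq_len(nPer * length(groups)))
  SampleDesign(setNames(rep(groups, each = nPer), ids), groups)
}

smallParams <- function(seed = 1L) {
  SimulationParams(nMirna = 120L, nMrna = 400L, nDeMirnaPerComparison = 8L,
                   targetsPerDeMirna = 3L, nTerms = 12L, seed = seed)
}

.simStore <- new.env(parent = emptyenv())

cachedSim <- function(seed, small = TRUE) {
  key <- paste0(if (small) "s" else "d", seed)
  if (is.null(.simStore[[key]])) {
    params <- if (small) smallParams(seed) else SimulationParams(seed = seed)
    .simStore[[key]] <- simulateDataset(params)
  }
  .simStore[[key]]
}

## Ordinary pooled two-sample t, written from the textbook formula;
## independent oracle for the no-moderation limit and the qPCR statistics.
pooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Brute-force BH from the step-up definition displayed in the docs.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[ord[seq.int(j, m)]] /
                           seq.int(j, m)))
  }
  adj
}
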