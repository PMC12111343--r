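## Config-driven orchestration: simulate (or load) -> preprocess -> DE over
## all comparisons -> pairs -> enrichment -> clustering -> optional
## concordance, writing a single results directory.

#' Default pipeline configuration
#'
#' Returns the configuration list that \code{\link{runPipeline}} consumes:
#' the threshold block (fold 2, raw p 0.05, FDR 0.20, >= 3 sources, core
#' correlation 0.8, enrichment alpha 0.05), the seven default comparisons,
#' the preprocessing switches and, by default, the synthetic-data generator
#' as the input source. Supply \code{inputs} (paths to mirna / mrna /
#' design / targets / gene_sets files) instead of \code{simulation} to run
#' on real data.
#'
#' @param seed Master seed; every randomised stage draws a named substream
#'   from it via \code{\link{stageSeed}}.
#' @return A named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(),             # args to SimulationParams(); NULL = load
    inputs = NULL,                   # list(mirna=, mrna=, design=, targets=, gene_sets=)
    preprocess = list(quantile_normalize = TRUE, variance_quantile = 0),
    thresholds = list(fc = 2, p = 0.05, fdr = 0.20, min_sources = 3L,
                      core_corr = 0.8, alpha = 0.05),
    comparisons = NULL,              # NULL = the seven default contrasts
    cluster = list(k = "auto", k_max = 8L, n_init = 25L, scale_rows = TRUE),
    concordance = NULL)              # list(other = path, comparison = name)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: '%s'", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(seed = user$seed %||% 1L)
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      for (sub in names(user[[key]])) cfg[[key]][[sub]] <- user[[key]][[sub]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.safeName <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Run the full integrative pipeline
#'
#' Executes simulate/load -> preprocess -> differential expression over
#' every configured comparison -> target aggregation and pair calling ->
#' per-comparison enrichment -> co-expression clustering (elbow-selected k
#' unless fixed) -> optional external concordance, writing all tables, a
#' run log and a manifest under \code{outDir}. Any stage error aborts with
#' the stage name. Re-running with the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param config Configuration list (see \code{\link{defaultPipelineConfig}}).
#' @param outDir Output directory (created if absent).
#' @param verbose Emit timestamped progress lines to the console.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of everything written.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        verbose = FALSE) {
  stopifnot(is.list(config), !missing(outDir))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0L)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    if (verbose) message(format(Sys.time(), "%H:%M:%S "), line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  th <- config$thresholds
  seed <- config$seed

  ## ---- inputs ------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", {
      args <- config$simulation
      args$seed <- stageSeed(seed, "simulate")
      simData <- do.call(SimulationParams, args)
      out <- simulateDataset(simData)
      dir.create(file.path(outDir, "inputs"), showWarnings = FALSE)
      writeExpressionMatrix(out$mirna, file.path(outDir, "inputs", "mirna.tsv"))
      writeExpressionMatrix(out$mrna, file.path(outDir, "inputs", "mrna.tsv"))
      writeSampleDesign(out$design, file.path(outDir, "inputs", "design.tsv"))
      writeTargetTable(out$targets, file.path(outDir, "inputs", "targets.tsv"))
      writeGeneSets(out$geneSets, file.path(outDir, "inputs", "gene_sets.gmt"))
      writeTruth(out$truth, file.path(outDir, "inputs", "truth.json"))
      note("simulate: %d miRNAs, %d mRNAs, %d samples",
           nrow(out$mirna), nrow(out$mrna), ncol(out$mirna))
      out
    })
    mirna <- sim$mirna; mrna <- sim$mrna; design <- sim$design
    geneSets <- sim$geneSets
  } else {
    inp <- config$inputs
    mirna <- stage("inputs", readExpressionMatrix(inp$mirna, "log2"))
    mrna <- stage("inputs", readExpressionMatrix(inp$mrna, "log2"))
    design <- stage("inputs", readSampleDesign(inp$design))
    geneSets <- stage("inputs", readGeneSets(inp$gene_sets))
    note("inputs: %d miRNAs, %d mRNAs, %d samples",
         nrow(mirna), nrow(mrna), ncol(mirna))
  }

  ## ---- preprocess --------------------------------------------------------
  pp <- config$preprocess
  mirna <- stage("preprocess", {
    nIn <- nrow(mirna)
    if (isTRUE(pp$quantile_normalize)) mirna <- quantileNormalize(mirna)
    if ((pp$variance_quantile %||% 0) > 0)
      mirna <- filterLowVariance(mirna, pp$variance_quantile)
    note("preprocess (miRNA): %d features in, %d out", nIn, nrow(mirna))
    mirna
  })
  mrna <- stage("preprocess", {
    nIn <- nrow(mrna)
    if (isTRUE(pp$quantile_normalize)) mrna <- quantileNormalize(mrna)
    if ((pp$variance_quantile %||% 0) > 0)
      mrna <- filterLowVariance(mrna, pp$variance_quantile)
    note("preprocess (mRNA): %d features in, %d out", nIn, nrow(mrna))
    mrna
  })

  comparisons <- config$comparisons %||% defaultComparisons()
  comparisons <- lapply(comparisons, function(cmp) {
    if (is(cmp, "Comparison")) cmp else Comparison(cmp[[1L]], cmp[[2L]])
  })

  ## ---- differential expression -------------------------------------------
  deDir <- file.path(outDir, "de"); dir.create(deDir, showWarnings = FALSE)
  deMirna <- list(); deMrna <- list()
  for (cmp in comparisons) {
    stage("de", {
      resM <- callDifferential(moderatedTTest(mirna, design, cmp),
                               th$fc, th$p, th$fdr)
      resG <- callDifferential(moderatedTTest(mrna, design, cmp),
                               th$fc, th$p, th$fdr)
      deMirna[[cmp@name]] <- resM; deMrna[[cmp@name]] <- resG
      base <- .safeName(cmp@name)
      .writeTsv(cbind(feature = rownames(resM), as.data.frame(resM)),
                file.path(deDir, paste0(base, "_mirna.tsv")))
      .writeTsv(cbind(feature = rownames(resG), as.data.frame(resG)),
                file.path(deDir, paste0(base, "_mrna.tsv")))
      .writeTsv(volcanoTable(resM),
                file.path(deDir, paste0(base, "_volcano_mirna.tsv")))
      cnt <- deCounts(resM)
      jsonlite::write_json(list(n_down = cnt[["down"]], n_up = cnt[["up"]]),
                           file.path(deDir, paste0(base, "_summary.json")),
                           auto_unbox = TRUE, digits = NA)
      note("de %s: miRNA %d down / %d up; mRNA %d down / %d up",
           cmp@name, cnt[["down"]], cnt[["up"]],
           deCounts(resG)[["down"]], deCounts(resG)[["up"]])
    })
  }

  ## ---- target aggregation and pair calling -------------------------------
  pairsDir <- file.path(outDir, "pairs")
  dir.create(pairsDir, showWarnings = FALSE)
  agg <- stage("pairs", {
    targets <- if (!is.null(sim)) sim$targets
      else readTargetTable(config$inputs$targets)
    aggregateTargets(targets, th$min_sources)
  })
  pairTables <- list()
  for (cmp in comparisons) {
    stage("pairs", {
      pr <- callPairs(deMirna[[cmp@name]], deMrna[[cmp@name]], agg, cmp)
      pairTables[[cmp@name]] <- pr
      .writeTsv(pr, file.path(pairsDir,
                              paste0(.safeName(cmp@name), "_pairs.tsv")))
      note("pairs %s: %d anti-correlated pairs", cmp@name, nrow(pr))
    })
  }

  ## ---- enrichment ---------------------------------------------------------
  enrDir <- file.path(outDir, "enrich")
  dir.create(enrDir, showWarnings = FALSE)
  enrich <- list()
  for (cmp in comparisons) {
    stage("enrich", {
      genes <- pairGeneSet(pairTables[[cmp@name]])
      genes <- intersect(genes, geneUniverse(geneSets))
      base <- .safeName(cmp@name)
      if (length(genes) == 0L) {
        enr <- data.frame()
        note("enrich %s: no paired genes in the universe", cmp@name)
      } else {
        enr <- hypergeometricEnrichment(genes, geneSets)
        note("enrich %s: %d/%d terms below alpha", cmp@name,
             sum(enr$p_adj < th$alpha), nrow(enr))
      }
      enrich[[cmp@name]] <- enr
      .writeTsv(enr, file.path(enrDir, paste0(base, "_enrichment.tsv")))
      if (nrow(enr) > 0L)
        .writeTsv(bubbleExport(enr, th$alpha),
                  file.path(enrDir, paste0(base, "_bubble.tsv")))
    })
  }

  ## ---- co-expression clustering ------------------------------------------
  clDir <- file.path(outDir, "cluster")
  dir.create(clDir, showWarnings = FALSE)
  clusterOut <- stage("cluster", {
    feats <- intersect(selectClusteringFeatures(deMirna), rownames(mirna))
    note("cluster: %d significantly regulated miRNAs selected", length(feats))
    if (length(feats) < 3L) {
      note("cluster: too few regulated miRNAs, stage skipped")
      NULL
    } else {
    cl <- config$cluster
    prof <- groupMeanProfile(mirna, design, feats)
    if (isTRUE(cl$scale_rows)) prof <- zscoreRows(prof)
    kMax <- min(cl$k_max %||% 8L, nrow(prof))
    clSeed <- stageSeed(seed, "cluster")
    curve <- sseCurve(prof, kMax, seed = clSeed, nInit = cl$n_init %||% 25L)
    .writeTsv(curve, file.path(clDir, "sse_curve.tsv"))
    k <- cl$k %||% "auto"
    if (identical(k, "auto")) {
      if (nrow(curve) >= 3L) k <- chooseKElbow(curve)$k else k <- 1L
    }
    model <- kmeansCluster(prof, k, seed = clSeed,
                           nInit = cl$n_init %||% 25L)
    model <- extractCore(model, prof, th$core_corr)
    assignTab <- data.frame(feature = names(clusterAssignments(model)),
                            cluster = unname(clusterAssignments(model)))
    coreTab <- do.call(rbind, lapply(seq_len(model@k), function(i) {
      co <- coreMembers(model)[[i]]
      if (nrow(co) == 0L) return(NULL)
      cbind(cluster = i, co)
    }))
    .writeTsv(assignTab, file.path(clDir, "clusters.tsv"))
    .writeTsv(coreTab %||% data.frame(cluster = integer(0L),
                                      feature = character(0L),
                                      r = numeric(0L)),
              file.path(clDir, "core_members.tsv"))
    hm <- heatmapExport(mirna, design, model, deMirna)
    for (panel in c("mean_scaled", "sample_scaled", "fold_change"))
      .writeTsv(cbind(feature = hm$features, cluster = hm$cluster,
                      as.data.frame(hm[[panel]])),
                file.path(clDir, paste0("heatmap_", panel, ".tsv")))
    note("cluster: k = %d, SSE = %.4g, core sizes [%s]", model@k,
         clusterSse(model),
         paste(vapply(coreMembers(model), nrow, integer(1L)),
               collapse = ", "))
    list(model = model, curve = curve, profiles = prof)
    }
  })

  pca <- stage("cluster", {
    sc <- pcaScores(mirna)
    .writeTsv(data.frame(sample = rownames(sc$scores), sc$scores,
                         check.names = FALSE),
              file.path(clDir, "pca_scores.tsv"))
    sc
  })

  ## ---- concordance --------------------------------------------------------
  concord <- NULL
  if (!is.null(config$concordance)) {
    concord <- stage("concord", {
      other <- utils::read.delim(config$concordance$other, sep = "\t",
                                 stringsAsFactors = FALSE)
      cmpName <- config$concordance$comparison %||%
        names(deMirna)[[length(deMirna)]]
      res <- directionConcordance(deMirna[[cmpName]], other,
                                  alpha = th$alpha)
      .writeTsv(res$table, file.path(outDir, "concordance.tsv"))
      jsonlite::write_json(list(n_common = res$n_common,
                                concordant_fraction = res$concordant_fraction),
                           file.path(outDir, "concordance_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      note("concord %s: %d common, %.3f concordant", cmpName, res$n_common,
           res$concordant_fraction)
      res
    })
  }

  ## ---- manifest and log ---------------------------------------------------
  writeLines(logLines, file.path(outDir, "run.log"))
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(package = "miRPair",
                   version = as.character(utils::packageVersion("miRPair")),
                   seed = seed,
                   config = config,
                   files = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(de_mirna = deMirna, de_mrna = deMrna, pairs = pairTables,
                 enrichment = enrich, cluster = clusterOut, pca = pca,
                 concordance = concord, simulated = sim, outDir = outDir))
}
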