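## Shared 20-seed recovery study at generator defaults. Computed once and
## cached so the recovery properties (DE, pairs, clustering, enrichment) all
## read from the same runs.

.studyStore <- new.env(parent = emptyenv())

recoveryStudy <- function(nSeeds = 20L) {
  key <- paste0("n", nSeeds)
  if (!is.null(.studyStore[[key]])) return(.studyStore[[key]])
  headline <- "ORX+T vs OVX+E"
  rows <- lapply(seq_len(nSeeds), function(s) {
    sim <- simulateDataset(SimulationParams(seed = s))
    agg <- aggregateTargets(sim$targets, 3L)
    tp <- tgt <- fp <- called <- 0L
    fpAll <- nullAll <- 0L
    signViolations <- 0L
    pairStats <- NULL
    deTables <- list()
    for (cmp in defaultComparisons()) {
      resM <- callDifferential(moderatedTTest(sim$mirna, sim$design, cmp))
      resG <- callDifferential(moderatedTTest(sim$mrna, sim$design, cmp))
      deTables[[cmp@name]] <- resM
      dm <- deRecovery(resM, sim$truth, cmp@name)
      dg <- deRecovery(resG, sim$truth, cmp@name)
      tp <- tp + dm$tp; tgt <- tgt + dm$n_target
      fp <- fp + dm$fp; called <- called + dm$n_called
      planted <- plantedDeSets(sim$truth)[[cmp@name]]
      fpAll <- fpAll + dm$fp + dg$fp
      nullAll <- nullAll +
        (nrow(sim$mirna) + nrow(sim$mrna) - length(planted))
      pairs <- callPairs(resM, resG, agg, cmp)
      signViolations <- signViolations +
        sum(pairs$mirna_log2fc * pairs$gene_log2fc >= 0)
      if (cmp@name == headline)
        pairStats <- c(pairRecovery(pairs, sim$truth, cmp@name),
                       list(pairs = pairs))
    }
    ## decoy emission rate: emitted non-edge pairs over available decoy pairs
    aggKeys <- paste(targetRecords(agg)$mirna, targetRecords(agg)$gene)
    edgeKeys <- paste(plantedEdges(sim$truth)$mirna,
                      plantedEdges(sim$truth)$gene)
    nDecoyAvailable <- sum(!aggKeys %in% edgeKeys)

    ## clustering on the selected significant miRNAs
    feats <- selectClusteringFeatures(deTables)
    prof <- zscoreRows(groupMeanProfile(sim$mirna, sim$design, feats))
    curve <- sseCurve(prof, 8L, seed = s + 5000L)
    elbowK <- chooseKElbow(curve)$k
    model <- extractCore(kmeansCluster(prof, 2L, seed = s + 5000L), prof)
    truthLab <- clusterLabels(sim$truth)
    common <- intersect(names(clusterAssignments(model)), names(truthLab))
    ari <- mclust::adjustedRandIndex(clusterAssignments(model)[common],
                                    truthLab[common])
    coreR <- unlist(lapply(coreMembers(model), function(df) df$r))

    ## enrichment of the recovered pair genes in the headline comparison
    genes <- intersect(pairGeneSet(pairStats$pairs),
                       geneUniverse(sim$geneSets))
    enr <- hypergeometricEnrichment(genes, sim$geneSets)
    plantedP <- max(enr$p_adj[enr$term_id %in% enrichedTerms(sim$truth)])

    list(sensitivity = tp / tgt,
         fdr = if (called > 0L) fp / called else 0,
         de_fp_rate = fpAll / nullAll,
         pair_recovery = pairStats$recovery,
         decoy_emitted = pairStats$n_decoy,
         decoy_available = nDecoyAvailable,
         sign_violations = signViolations,
         elbow_k = elbowK,
         sse_monotone = all(diff(curve$sse) <= 1e-9),
         ari = ari,
         min_core_r = if (length(coreR) > 0L) min(coreR) else NA_real_,
         planted_term_p = plantedP)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  .studyStore[[key]] <- out
  out
}
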