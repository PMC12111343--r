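## Synthetic-data generator: coupled miRNA/mRNA matrices with planted
## differential expression, repressive target edges, gene-set enrichment and
## two co-expression archetypes, plus machine-readable ground truth.

## Group-shape vectors of the two planted archetypes, on the default
## six-group design. Archetype 1 peaks in ORX+T with mildly elevated male
## groups; archetype 2 is lowest in ORX+T and highest in OVX+E. Pairwise
## group differences are multiples of 0.5, so the per-feature amplitude
## multiplies to full strength in the ORX+T vs OVX+E contrast and half
## strength in the secondary contrasts.
.archetypeShapes <- function(groups) {
  s1 <- setNames(numeric(length(groups)), groups)
  s2 <- s1
  pick <- function(shape, values) {
    common <- intersect(names(values), names(shape))
    shape[common] <- values[common]
    shape
  }
  s1 <- pick(s1, c("Male C" = 0.5, "ORX" = 0.5, "ORX+T" = 1))
  s2 <- pick(s2, c("Male C" = 0.5, "Female C" = 0.5, "ORX" = 0.5,
                   "OVX" = 0.5, "ORX+T" = 0, "OVX+E" = 1))
  if (all(s1 == 0)) s1[length(s1)] <- 1          # non-default group labels
  if (all(s2 == 0)) s2[1L] <- 1
  list(s1, s2)
}

## Per-feature residual SDs from a scaled inverse-chi-square prior,
## tau^2 ~ priorDf * noiseSd^2 / chisq(priorDf); degenerate at noiseSd = 0.
.drawNoiseSd <- function(n, noiseSd, priorDf) {
  if (noiseSd == 0) return(rep(0, n))
  sqrt(priorDf * noiseSd^2 / stats::rchisq(n, df = priorDf))
}

#' Simulate a coupled miRNA/mRNA dataset with planted truth
#'
#' Generates log2-scale miRNA and mRNA expression matrices over the
#' six-group, three-replicate design, a multi-database ranked target table, a
#' GMT-style gene-set collection and a \linkS4class{SyntheticTruth} recording
#' everything that was planted. Per-feature values are
#' baseline + group effect + Gaussian noise whose per-feature variance is
#' drawn from a scaled inverse-chi-square prior, so the moderated-t model
#' downstream is well specified.
#'
#' Planted miRNAs belong to one of two archetypes realised as additive
#' group-effect vectors (peak in ORX+T; trough in ORX+T / peak in OVX+E).
#' Each planted miRNA represses \code{targetsPerDeMirna} genes with an
#' opposite-sign effect of comparable magnitude, and the planted edges appear
#' in at least \code{minPlantedSources} databases with ranks 1..k. The table
#' also carries under-supported edges (below the source threshold) and decoy
#' edges between unregulated features, giving pair calling a non-trivial
#' false-positive surface. One gene-set term per archetype consists of that
#' archetype's target genes and is therefore planted as enriched.
#'
#' @param params A \linkS4class{SimulationParams}.
#' @return A list with elements \code{mirna}, \code{mrna}
#'   (\linkS4class{ExpressionMatrix}), \code{design}
#'   (\linkS4class{SampleDesign}), \code{targets} (\linkS4class{TargetTable}),
#'   \code{geneSets} (\linkS4class{GeneSetCollection}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- simulateDataset(SimulationParams(nMirna = 100L, nMrna = 300L,
#'                                         nDeMirnaPerComparison = 5L,
#'                                         seed = 7L))
#' sim$mirna
#' @export
simulateDataset <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  .withSeed(params@seed, .simulateDataset(params))
}

.simulateDataset <- function(p) {
  groups <- p@groups
  sampleIds <- unlist(lapply(groups, function(g)
    sprintf("%s_r%d", gsub("[ +]", "", g), seq_len(p@repsPerGroup))))
  sampleGroups <- rep(groups, each = p@repsPerGroup)
  design <- SampleDesign(setNames(sampleGroups, sampleIds), groups)

  mirnaIds <- sprintf("miR-%04d", seq_len(p@nMirna))
  geneIds <- sprintf("gene-%05d", seq_len(p@nMrna))
  shapes <- .archetypeShapes(groups)

  nDe <- p@nDeMirnaPerComparison
  planted <- if (nDe > 0L) sample(p@nMirna, 2L * nDe) else integer(0L)
  archetype <- setNames(rep(c(1L, 2L), each = nDe), mirnaIds[planted])

  ## group-effect matrices (features x groups)
  effM <- matrix(0, p@nMirna, length(groups),
                 dimnames = list(mirnaIds, groups))
  amp <- stats::runif(length(planted), p@effectLow, p@effectHigh)
  names(amp) <- mirnaIds[planted]
  for (i in seq_along(planted))
    effM[planted[i], ] <- amp[i] * shapes[[archetype[i]]]

  effG <- matrix(0, p@nMrna, length(groups), dimnames = list(geneIds, groups))
  edges <- data.frame(mirna = character(0L), gene = character(0L),
                      sign = integer(0L), stringsAsFactors = FALSE)
  if (length(planted) > 0L && p@targetsPerDeMirna > 0L) {
    targetIdx <- sample(p@nMrna, length(planted) * p@targetsPerDeMirna)
    edges <- data.frame(
      mirna = rep(mirnaIds[planted], each = p@targetsPerDeMirna),
      gene = geneIds[targetIdx], sign = -1L, stringsAsFactors = FALSE)
    jitter <- stats::runif(nrow(edges), 1 - p@repressionJitter,
                           1 + p@repressionJitter)
    for (e in seq_len(nrow(edges))) {
      m <- edges$mirna[e]
      effG[edges$gene[e], ] <- -jitter[e] * amp[m] * shapes[[archetype[m]]]
    }
  }

  ## expression values = baseline + group effect + N(0, tau_f)
  drawMatrix <- function(ids, eff) {
    n <- length(ids)
    baseline <- stats::rnorm(n, p@baselineMean, p@baselineSd)
    tau <- .drawNoiseSd(n, p@noiseSd, p@priorDf)
    noise <- matrix(stats::rnorm(n * length(sampleIds)), n) * tau
    vals <- baseline + eff[, sampleGroups, drop = FALSE] + noise
    dimnames(vals) <- list(ids, sampleIds)
    ExpressionMatrix(vals, "log2")
  }
  mirna <- drawMatrix(mirnaIds, effM)
  mrna <- drawMatrix(geneIds, effG)

  ## planted truth per comparison
  comparisons <- Filter(function(cmp)
    cmp@groupA %in% groups && cmp@groupB %in% groups, defaultComparisons())
  if (length(comparisons) == 0L)
    comparisons <- list(Comparison(groups[1L], groups[2L]))
  deSets <- list(); pairSets <- list()
  for (cmp in comparisons) {
    dM <- effM[, cmp@groupA] - effM[, cmp@groupB]
    dG <- effG[, cmp@groupA] - effG[, cmp@groupB]
    deSets[[cmp@name]] <- c(dM[dM != 0], dG[dG != 0])
    if (nrow(edges) > 0L) {
      ok <- abs(dM[edges$mirna]) >= p@effectLow &
        abs(dG[edges$gene]) >= p@effectLow
      pairSets[[cmp@name]] <- edges[ok, c("mirna", "gene"), drop = FALSE]
    } else {
      pairSets[[cmp@name]] <- data.frame(mirna = character(0L),
                                         gene = character(0L))
    }
    rownames(pairSets[[cmp@name]]) <- NULL
  }

  targets <- .simulateTargetTable(p, edges, mirnaIds, geneIds,
                                  names(archetype))
  geneSets <- .simulateGeneSets(p, edges, archetype, geneIds)

  truth <- new("SyntheticTruth", deSets = deSets, edges = edges,
               pairs = pairSets, clusterLabels = archetype,
               enrichedTerms = geneSets$enriched)

  list(mirna = mirna, mrna = mrna, design = design, targets = targets,
       geneSets = geneSets$collection, truth = truth)
}

## Target table: planted edges under >= minPlantedSources databases,
## under-supported edges below the threshold, and decoy edges between
## unregulated miRNAs and genes making up about `decoyFraction` of rows.
.simulateTargetTable <- function(p, edges, mirnaIds, geneIds, plantedMirnas) {
  sources <- c("DIANA", "Miranda", "PicTar", "TargetScan", "miRWalk")
  if (p@nSources > length(sources))
    sources <- c(sources, sprintf("source%d", seq_len(p@nSources - length(sources))))
  sources <- sources[seq_len(p@nSources)]

  rows <- list()
  addEdge <- function(m, g, nsrc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mirna = m, gene = g, source = sample(sources, nsrc),
      stringsAsFactors = FALSE)
  }
  srcRange <- p@minPlantedSources:p@nSources
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges)))
      addEdge(edges$mirna[e], edges$gene[e],
              if (length(srcRange) == 1L) srcRange else sample(srcRange, 1L))

    ## under-supported edges: planted miRNA -> untargeted gene, < min sources
    if (p@minPlantedSources > 1L) {
      nUnder <- max(1L, round(0.05 * nrow(edges)))
      freeGenes <- setdiff(geneIds, edges$gene)
      um <- sample(plantedMirnas, nUnder, replace = TRUE)
      ug <- sample(freeGenes, nUnder)
      for (e in seq_len(nUnder))
        addEdge(um[e], ug[e], sample.int(p@minPlantedSources - 1L, 1L))
    }
  }

  ## decoys: unregulated miRNA -> unregulated gene with full source support
  nRowsSoFar <- sum(vapply(rows, nrow, integer(1L)))
  if (p@decoyFraction > 0 && nRowsSoFar > 0L) {
    targetRows <- p@decoyFraction / (1 - p@decoyFraction) * nRowsSoFar
    meanSrc <- mean(srcRange)
    nDecoy <- max(1L, round(targetRows / meanSrc))
    freeM <- setdiff(mirnaIds, plantedMirnas)
    freeG <- setdiff(geneIds, edges$gene)
    dm <- sample(freeM, nDecoy, replace = TRUE)
    dg <- sample(freeG, min(nDecoy, length(freeG)))
    for (e in seq_len(min(length(dm), length(dg))))
      addEdge(dm[e], dg[e],
              if (length(srcRange) == 1L) srcRange else sample(srcRange, 1L))
  }

  if (length(rows) == 0L)
    return(TargetTable(data.frame(mirna = character(0L), gene = character(0L),
                                  source = character(0L), rank = integer(0L))))
  tab <- do.call(rbind, rows)
  ## drop accidental duplicate (mirna, gene, source) triples from decoy reuse
  tab <- tab[!duplicated(paste(tab$mirna, tab$gene, tab$source, sep = "\r")), ]
  ## within each (source, miRNA) list, assign a random permutation of 1..k
  tab$rank <- NA_integer_
  for (idx in split(seq_len(nrow(tab)),
                    paste(tab$source, tab$mirna, sep = "\r")))
    tab$rank[idx] <- sample.int(length(idx))
  rownames(tab) <- NULL
  TargetTable(tab)
}

## Gene sets: one planted term per archetype (its target genes) plus random
## terms drawn from the assayed genes.
.simulateGeneSets <- function(p, edges, archetype, geneIds) {
  nEnriched <- max(1L, round(p@enrichedTermFraction * p@nTerms))
  nEnriched <- min(nEnriched, p@nTerms)
  sets <- list(); termNames <- character(0L); enriched <- character(0L)
  for (i in seq_len(p@nTerms)) {
    id <- sprintf("TERM:%04d", i)
    if (i <= nEnriched && nrow(edges) > 0L) {
      arch <- ((i - 1L) %% 2L) + 1L
      members <- unique(edges$gene[archetype[edges$mirna] == arch])
      if (length(members) == 0L)
        members <- unique(edges$gene)
      sets[[id]] <- members
      termNames[id] <- sprintf("planted archetype-%d target program", arch)
      enriched <- c(enriched, id)
    } else {
      size <- sample(50:200, 1L)
      sets[[id]] <- sample(geneIds, min(size, length(geneIds)))
      termNames[id] <- sprintf("synthetic process %d", i)
    }
  }
  list(collection = GeneSetCollection(sets, termNames),
       enriched = enriched)
}
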