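## Readers and writers for every tabular format the pipeline touches.
## All formats are TAB-separated with a mandatory header row; readers reject
## invariant violations rather than repairing them.

#' Read / write an expression matrix
#'
#' TSV layout: first column \code{feature_id}, remaining columns one per
#' sample. Duplicated ids, non-numeric cells, missing values and ragged rows
#' are hard errors.
#'
#' @param path File path.
#' @param scale \code{"log2"} or \code{"linear"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  tab <- .readTsv(path)
  if (ncol(tab) < 2L) .stopf("expression table needs at least one sample column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    .stopf("duplicated feature id '%s' in '%s'", ids[duplicated(ids)][1L], path)
  vals <- vapply(seq.int(2L, ncol(tab)),
                 function(j) .numericColumn(tab[[j]], names(tab)[j],
                                            sprintf("'%s'", path)),
                 numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, names(tab)[-1L]))
  ExpressionMatrix(vals, scale)
}

#' @rdname readExpressionMatrix
#' @param m An ExpressionMatrix to write.
#' @export
writeExpressionMatrix <- function(m, path) {
  stopifnot(is(m, "ExpressionMatrix"))
  v <- exprValues(m)
  df <- data.frame(feature_id = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Read / write a sample design
#'
#' TSV columns: \code{sample_id}, \code{group}. Group order is the order of
#' first appearance. A sample listed twice is an error.
#'
#' @param path File path.
#' @return A \linkS4class{SampleDesign}.
#' @export
readSampleDesign <- function(path) {
  tab <- .readTsv(path)
  if (!all(c("sample_id", "group") %in% names(tab)))
    .stopf("design table needs columns 'sample_id' and 'group'")
  if (anyDuplicated(tab$sample_id))
    .stopf("sample '%s' listed more than once in '%s'",
           tab$sample_id[duplicated(tab$sample_id)][1L], path)
  SampleDesign(setNames(tab$group, tab$sample_id), unique(tab$group))
}

#' @rdname readSampleDesign
#' @param design A SampleDesign to write.
#' @export
writeSampleDesign <- function(design, path) {
  stopifnot(is(design, "SampleDesign"))
  .writeTsv(data.frame(sample_id = names(design@assignments),
                       group = unname(design@assignments)), path)
  invisible(path)
}

#' Read / write a ranked target table
#'
#' TSV columns: \code{mirna}, \code{gene}, \code{source}, \code{rank}. Ranks
#' must be positive integers, unique within each (source, miRNA) list and
#' starting at 1; duplicate (miRNA, gene, source) triples are errors.
#'
#' @param path File path.
#' @return A \linkS4class{TargetTable}.
#' @export
readTargetTable <- function(path) {
  tab <- .readTsv(path)
  need <- c("mirna", "gene", "source", "rank")
  if (!all(need %in% names(tab)))
    .stopf("target table needs columns %s", paste(need, collapse = ", "))
  rank <- .numericColumn(tab$rank, "rank", sprintf("'%s'", path))
  if (any(rank != round(rank)) || any(rank < 1))
    .stopf("ranks must be integers >= 1 (offending value: %s)",
           format(rank[which(rank != round(rank) | rank < 1)[1L]]))
  TargetTable(data.frame(mirna = tab$mirna, gene = tab$gene,
                         source = tab$source, rank = as.integer(rank),
                         stringsAsFactors = FALSE))
}

#' @rdname readTargetTable
#' @param targets A TargetTable to write.
#' @export
writeTargetTable <- function(targets, path) {
  stopifnot(is(targets, "TargetTable"))
  .writeTsv(targets@records, path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT dialect: \code{term_id TAB description TAB gene TAB gene...}.
#' A line with fewer than three fields (i.e. an empty gene list) is an error
#' reported with its line number.
#'
#' @param path GMT file path.
#' @param universe Optional explicit gene universe (character vector); by
#'   default the union of all member genes.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path, universe = NULL) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) .stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    .stopf("GMT line %d has fewer than 3 fields", short[1L])
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    .stopf("duplicated term id '%s'", ids[duplicated(ids)][1L])
  sets <- setNames(lapply(fields, function(f) f[-c(1L, 2L)]), ids)
  termNames <- setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  GeneSetCollection(sets, termNames, universe)
}

#' @rdname readGeneSets
#' @param sets A GeneSetCollection to write.
#' @export
writeGeneSets <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(names(sets@sets), function(id) {
    paste(c(id, unname(sets@termNames[[id]]), sets@sets[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a qPCR Ct table
#'
#' Long TSV layout, columns \code{sample_id}, \code{gene}, \code{ct}. Every
#' sample must carry a Ct for the reference gene; values must be finite and
#' positive.
#'
#' @param path File path.
#' @param design A \linkS4class{SampleDesign} covering the Ct samples.
#' @param referenceGene Name of the reference gene (e.g. \code{"RNU1A1"}).
#' @return A \linkS4class{CtTable}.
#' @export
readCtTable <- function(path, design, referenceGene) {
  tab <- .readTsv(path)
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(tab)))
    .stopf("Ct table needs columns %s", paste(need, collapse = ", "))
  ct <- .numericColumn(tab$ct, "ct", sprintf("'%s'", path))
  key <- paste(tab$gene, tab$sample_id, sep = "\r")
  if (anyDuplicated(key))
    .stopf("duplicate Ct measurement for gene '%s', sample '%s'",
           tab$gene[duplicated(key)][1L], tab$sample_id[duplicated(key)][1L])
  genes <- unique(tab$gene)
  samples <- unique(tab$sample_id)
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(tab$gene, genes), match(tab$sample_id, samples))] <- ct
  if (anyNA(mat))
    .stopf("incomplete Ct table: gene '%s' is missing in sample '%s'",
           rownames(mat)[which(is.na(mat), arr.ind = TRUE)[1L, 1L]],
           colnames(mat)[which(is.na(mat), arr.ind = TRUE)[1L, 2L]])
  CtTable(mat, referenceGene, design)
}

#' @rdname readCtTable
#' @param ct A CtTable to write.
#' @export
writeCtTable <- function(ct, path) {
  stopifnot(is(ct, "CtTable"))
  df <- expand.grid(gene = rownames(ct@ct), sample_id = colnames(ct@ct),
                    stringsAsFactors = FALSE)
  df$ct <- ct@ct[cbind(df$gene, df$sample_id)]
  .writeTsv(df[, c("sample_id", "gene", "ct")], path)
  invisible(path)
}

#' Read / write planted simulation truth
#'
#' JSON serialization of a \linkS4class{SyntheticTruth}; the round trip is
#' lossless.
#'
#' @param truth A SyntheticTruth.
#' @param path File path.
#' @return \code{readTruth} returns a \linkS4class{SyntheticTruth}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  payload <- list(
    de_sets = lapply(truth@deSets, as.list),
    edges = truth@edges,
    pairs = truth@pairs,
    cluster_labels = as.list(truth@clusterLabels),
    enriched_terms = truth@enrichedTerms)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("de_sets", "edges", "pairs", "cluster_labels", "enriched_terms")
  if (!all(need %in% names(p)))
    .stopf("truth file is missing field '%s'", setdiff(need, names(p))[1L])
  asNamedNum <- function(x) {
    if (length(x) == 0L) return(numeric(0L))
    unlist(x)
  }
  edges <- as.data.frame(p$edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(mirna = character(0L), gene = character(0L),
                        sign = integer(0L))
  pairs <- lapply(p$pairs, function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
      df <- data.frame(mirna = character(0L), gene = character(0L))
    df
  })
  new("SyntheticTruth",
      deSets = lapply(p$de_sets, asNamedNum),
      edges = edges,
      pairs = pairs,
      clusterLabels = vapply(p$cluster_labels, as.integer, integer(1L)),
      enrichedTerms = as.character(unlist(p$enriched_terms)))
}
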