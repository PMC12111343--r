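## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. All randomised entry points funnel through this.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named per-stage RNG substream from one master seed
#'
#' A single pipeline seed feeds every randomised stage through a distinct,
#' deterministic offset keyed by the stage name, so that stage-level results
#' are reproducible independently of stage order.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. \code{"simulate"}, \code{"cluster"}).
#' @return An integer seed below \code{2^31}.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) + 1009 * h) %% (.Machine$integer.max - 1L)) + 1L
}

## Newton inversion of the trigamma function, used by the variance-prior
## moment estimator. Tolerance 1e-8 on the relative step.
.trigammaInverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(60L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

## Strict TSV reader: all cells character, hard error on ragged rows.
.readTsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, fill = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

## Convert a character column to numeric, naming the offending cell on failure.
.numericColumn <- function(x, colname, what = "table") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L)
    .stopf("non-numeric value '%s' in %s at row %d, column '%s'",
           x[bad[1L]], what, bad[1L], colname)
  if (anyNA(out))
    .stopf("missing value in %s, column '%s'", what, colname)
  out
}
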