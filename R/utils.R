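#' @importFrom methods new is validObject slot show
#' @importFrom stats rnorm runif rlnorm rnbinom qbeta pnorm pt phyper pwilcox
#'   lm coef resid fitted cor sd var glm binomial predict quantile p.adjust
#'   complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage/per-iteration seed derivation. Keeps all derived
## seeds in [1, 2^31 - 2] and within exact double arithmetic (< 2^53).
seedStream <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  v <- (s * 1009 + as.double(index) * 9176 + 1) %% m
  as.integer(v %% (m - 1) + 1)
}

readTSV <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

writeTSV <- function(x, path, rowNames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = rowNames, col.names = TRUE)
}

#' Read or write a gene-set file (one identifier per line)
#'
#' @param path file path.
#' @return `readGeneSet` returns a character vector of identifiers.
#' @export
readGeneSet <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (anyDuplicated(x))
    stop("duplicate identifiers in gene-set file: ", path)
  x
}

#' @rdname readGeneSet
#' @param genes character vector of gene identifiers.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

## Group vocabulary for the queen-removal study design.
casteGroups <- function() c("queen", "control_worker", "qr_day3", "qr_day12")
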