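#' Read a gene x sample count matrix from TSV
#'
#' Expects genes as rows with identifiers in the first column and a header
#' row of sample identifiers. Identifiers must be unique and counts
#' nonnegative integers.
#'
#' @param path TSV path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path) {
  tab <- readTSV(path)
  if (ncol(tab) < 2) stop("count table needs a gene column and >= 1 sample")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count at gene ", genes[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV (genes as rows, first column `gene`)
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  writeTSV(df, path)
  invisible(path)
}

#' Read / write the per-sample metadata table
#'
#' Columns: `sample_id`, `group` (queen / control_worker / qr_day3 /
#' qr_day12), `age` (days), `ovarian_index`, `dominance`, `queenness`
#' (in [0, 1] or NA).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleTable <- function(path) {
  tab <- readTSV(path)
  need <- c("sample_id", "group", "age", "ovarian_index", "dominance",
            "queenness")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(as.character(tab$group)), casteGroups())
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  tab
}

#' @rdname readSampleTable
#' @param samples data.frame as returned by [readSampleTable()].
#' @export
writeSampleTable <- function(samples, path) {
  writeTSV(samples, path)
  invisible(path)
}

## Resolve (counts, samples) from either a CasteExperiment or a matrix +
## metadata data.frame.
resolveCounts_ <- function(counts, samples = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    se <- counts
    samples <- as.data.frame(SummarizedExperiment::colData(se))
    counts <- SummarizedExperiment::assay(se, "counts")
  }
  if (is.null(samples)) stop("sample metadata required")
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("count columns missing from sample table: ",
         paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  list(counts = counts, samples = samples)
}

#' Expression filter: >20 counts in at least one experimental group
#'
#' A gene is retained iff, for at least one of the four experimental groups
#' (queens, control workers, day-3 and day-12 post-removal workers), the sum
#' of its counts over that group's samples is strictly greater than 20.
#' Column set and gene order are preserved. Groups absent from the metadata
#' are skipped with a warning.
#'
#' @param counts integer count matrix (genes x samples) or a
#'   [CasteExperiment-class].
#' @param samples sample metadata data.frame (ignored when `counts` is a
#'   CasteExperiment).
#' @param threshold count-sum threshold (strict; default 20).
#' @return the filtered object, same type as the input.
#' @export
filterLowCounts <- function(counts, samples = NULL, threshold = 20) {
  inSE <- is(counts, "SummarizedExperiment")
  rc <- resolveCounts_(counts, samples)
  groups <- intersect(casteGroups(), unique(as.character(rc$samples$group)))
  if (length(groups) < length(casteGroups()))
    warning("group(s) absent, filter evaluated over groups present: ",
            paste(setdiff(casteGroups(), groups), collapse = ", "))
  if (length(groups) == 0) stop("no recognized experimental groups")
  keep <- rep(FALSE, nrow(rc$counts))
  for (g in groups) {
    idx <- which(rc$samples$group == g)
    keep <- keep | rowSums(rc$counts[, idx, drop = FALSE]) > threshold
  }
  if (inSE) counts[keep, ] else rc$counts[keep, , drop = FALSE]
}

#' log2 counts-per-million normalization
#'
#' value(g, i) = log2(count(g, i) * 1e6 / depth_i + pseudocount), where
#' depth_i is sample i's library size (column sum of the supplied, typically
#' already filtered, matrix). With the default pseudocount of 1 a zero count
#' maps to 0. The exact formula and per-sample depths are recorded in the
#' `normalization` attribute.
#'
#' @param counts count matrix (genes x samples) or [CasteExperiment-class].
#' @param pseudocount added inside the log (default 1).
#' @param depths optional externally supplied library sizes (named by
#'   sample); defaults to column sums.
#' @return numeric matrix of log2-CPM values with attribute `normalization`
#'   (list: formula, pseudocount, depths).
#' @export
normalizeLogCPM <- function(counts, pseudocount = 1, depths = NULL) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  depths <- depths %||% colSums(counts)
  if (any(depths == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[depths == 0], collapse = ", "))
  out <- log2(sweep(counts, 2, depths / 1e6, "/") + pseudocount)
  attr(out, "normalization") <- list(
    formula = "log2(count * 1e6 / depth + pseudocount)",
    pseudocount = pseudocount, depths = depths)
  out
}

#' Per-gene standardization fitted on training samples
#'
#' Centers and scales every gene to mean 0, unit variance across the
#' training samples. Genes with zero training variance are dropped (and
#' listed in the scaler) because they carry no discriminative signal and
#' would divide by zero. The scaler holds training statistics only; query
#' data are transformed with [applyStandardize()] using those statistics.
#'
#' @param x expression matrix, genes as ROWS (as produced by
#'   [normalizeLogCPM()]), samples as columns.
#' @return list with `x` (standardized samples x genes matrix, ready for the
#'   SVR engine) and `scaler` (list: center, scale, dropped).
#' @export
standardizeFeatures <- function(x) {
  if (ncol(x) < 2) stop("at least 2 training samples required")
  xt <- t(x)  # samples x genes
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, sd)
  dropped <- colnames(xt)[scl == 0 | !is.finite(scl)]
  keep <- setdiff(colnames(xt), dropped)
  xt <- xt[, keep, drop = FALSE]
  ctr <- ctr[keep]; scl <- scl[keep]
  z <- sweep(sweep(xt, 2, ctr, "-"), 2, scl, "/")
  list(x = z, scaler = list(center = ctr, scale = scl, dropped = dropped))
}

#' @rdname standardizeFeatures
#' @param scaler the scaler returned by [standardizeFeatures()].
#' @param query expression matrix (genes as rows, samples as columns) to
#'   transform with the TRAINING statistics.
#' @return samples x genes matrix on the training scale.
#' @export
applyStandardize <- function(scaler, query) {
  genes <- names(scaler$center)
  missing <- setdiff(genes, rownames(query))
  if (length(missing))
    stop("scaler genes absent from query: ", paste(missing, collapse = ", "))
  qt <- t(query[genes, , drop = FALSE])
  sweep(sweep(qt, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
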