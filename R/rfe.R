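#' Recursive feature elimination for caste-informative genes
#'
#' Starting from the full gene set, iterates the four-step loop: (1) record
#' the repeated k-fold cross-validation error of the current classifier;
#' (2) fit a classifier on all training samples and compute per-gene feature
#' weights ([featureWeights()], the matrix product of the dual coefficients
#' with the support vectors); (3) drop the single gene with the smallest
#' absolute weight (ties broken by canonical input gene order, first wins);
#' (4) refit on the remaining genes. The loop stops when `stopSize` genes
#' remain; that final set is also CV-evaluated.
#'
#' CV bins at iteration i are drawn from a seed derived from
#' `(seed, i)`, so re-running any suffix of the trace reproduces the same
#' randomness.
#'
#' @inheritParams crossValidationError
#' @param stopSize number of genes at which elimination stops (default 100).
#' @param batch optional integer: drop this many lowest-|weight| genes per
#'   iteration instead of one. Off (1) by default; the one-gene-per-iteration
#'   loop is the procedure of record and the only one the trace invariants
#'   describe.
#' @param verbose emit one log line per iteration
#'   (`iteration n_genes cv_error dropped_gene`).
#' @return an [RFETrace-class].
#' @export
runRFE <- function(x, y, spec, cost = 2^5, epsilon = 0.1, k = 3,
                   repeats = 20, stopSize = 100, seed = 1, batch = 1L,
                   verbose = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  genes <- colnames(x)
  if (stopSize >= length(genes))
    stop("stopSize (", stopSize, ") must be smaller than the number of genes (",
         length(genes), ")")
  if (stopSize < 1) stop("stopSize must be at least 1")
  batch <- max(1L, as.integer(batch))

  sets <- list()
  rows <- list()
  current <- genes
  i <- 0L
  repeat {
    i <- i + 1L
    xi <- x[, current, drop = FALSE]
    cv <- crossValidationError(xi, y, spec, cost = cost, epsilon = epsilon,
                               k = k, repeats = repeats,
                               seed = seedStream(seed, i))
    dropped <- NA_character_
    if (length(current) > stopSize) {
      fit <- fitSVR(xi, y, spec, cost = cost, epsilon = epsilon)
      w <- abs(featureWeights(fit))
      nd <- min(batch, length(current) - stopSize)
      ## order() is stable, so ties fall to the earlier gene in input order
      dropIdx <- order(w)[seq_len(nd)]
      dropped <- current[dropIdx[1]]
      droppedAll <- current[sort(dropIdx)]
    } else droppedAll <- character(0)
    sets[[i]] <- current
    rows[[i]] <- data.frame(iteration = i, n_genes = length(current),
                            cv_error = cv@meanError,
                            dropped_gene = dropped,
                            stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("rfe iteration=%d n_genes=%d cv_error=%.6f dropped_gene=%s",
                      i, length(current), cv@meanError,
                      if (is.na(dropped)) "-" else dropped))
    if (length(current) <= stopSize) break
    current <- setdiff(current, droppedAll)
  }
  new("RFETrace", iterations = do.call(rbind, rows), geneSets = sets,
      config = list(kind = spec@kind, gamma = spec@gamma,
                    degree = spec@degree, coef0 = spec@coef0, cost = cost,
                    epsilon = epsilon, k = k, repeats = repeats,
                    stop_size = stopSize, seed = seed, batch = batch))
}

#' Select the optimal classifier from an RFE trace
#'
#' Picks the iteration whose repeated-CV mean squared error is minimal (ties
#' go to the iteration with fewer genes) and refits the classifier on all
#' training samples restricted to that gene set.
#'
#' @param trace an [RFETrace-class].
#' @param x,y the training matrix and response the trace was computed from.
#' @return a [SelectedModel-class] (scaler/universe/normalization slots are
#'   filled by [trainCasteClassifier()]; empty here).
#' @export
selectOptimal <- function(trace, x, y) {
  stopifnot(is(trace, "RFETrace"))
  it <- trace@iterations
  best <- min(it$cv_error)
  cand <- which(it$cv_error == best)
  sel <- cand[which.min(it$n_genes[cand])]
  genes <- trace@geneSets[[sel]]
  cfg <- trace@config
  spec <- if (cfg$kind == "linear") kernelSpec("linear")
    else kernelSpec(cfg$kind, gamma = cfg$gamma, degree = cfg$degree,
                    coef0 = cfg$coef0)
  fit <- fitSVR(as.matrix(x)[, genes, drop = FALSE], y, spec,
                cost = cfg$cost, epsilon = cfg$epsilon)
  new("SelectedModel", model = fit, genes = genes,
      cvError = it$cv_error[sel], iteration = as.integer(sel),
      scaler = list(), universe = character(0), normalization = list())
}

#' Write an RFE trace as TSV
#'
#' @param trace an [RFETrace-class].
#' @param path output path.
#' @export
writeRFETrace <- function(trace, path) {
  stopifnot(is(trace, "RFETrace"))
  writeTSV(trace@iterations, path)
  invisible(path)
}
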