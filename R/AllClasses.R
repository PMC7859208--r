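#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' CasteExperiment: counts plus caste metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' integer gene x sample count matrix (assay `"counts"`) together with the
#' per-sample caste metadata the pipeline needs: `group` (one of `queen`,
#' `control_worker`, `qr_day3`, `qr_day12`), `age` (days), `ovarian_index`,
#' `dominance` (Elo-type rating) and `queenness` (probability-scale caste
#' score, possibly `NA` until fitted).
#'
#' @export
setClass("CasteExperiment", contains = "SummarizedExperiment")

setValidity("CasteExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "age", "ovarian_index", "dominance", "queenness")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if ("group" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$group)), casteGroups())
    if (length(bad))
      msg <- c(msg, paste("unknown group label(s):", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CasteExperiment
#'
#' @param counts integer matrix, genes as rows (rownames = gene identifiers),
#'   samples as columns (colnames = sample identifiers).
#' @param samples data.frame with columns `sample_id`, `group`, `age`,
#'   `ovarian_index`, `dominance`, `queenness`; every count column must be
#'   present in `sample_id`.
#' @return a [CasteExperiment-class] object with samples ordered as in
#'   `counts`.
#' @export
CasteExperiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("samples missing from metadata: ",
         paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("CasteExperiment", se)
}

#' Kernel specification for the SVR engine
#'
#' One of the four kernels used for classifier selection: `radial`
#' (\eqn{\exp(-\gamma |x-y|^2)}), `linear` (\eqn{x \cdot y}), `sigmoid`
#' (\eqn{\tanh(\gamma x \cdot y + c_0)}) and `polynomial`
#' (\eqn{(\gamma x \cdot y + c_0)^d}).
#'
#' @slot kind kernel family.
#' @slot gamma positive scale parameter (radial/sigmoid/polynomial).
#' @slot degree polynomial degree (>= 1).
#' @slot coef0 offset (sigmoid/polynomial).
#' @export
setClass("KernelSpec",
         representation(kind = "character", gamma = "numeric",
                        degree = "numeric", coef0 = "numeric"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("radial", "linear", "sigmoid", "polynomial"))
    msg <- c(msg, "kind must be radial, linear, sigmoid or polynomial")
  if (object@kind != "linear" &&
      (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0))
    msg <- c(msg, "gamma must be a positive scalar")
  if (object@kind == "polynomial" &&
      (object@degree < 1 || object@degree != round(object@degree)))
    msg <- c(msg, "degree must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param kind kernel family: `"radial"`, `"linear"`, `"sigmoid"` or
#'   `"polynomial"`.
#' @param gamma positive scale parameter; ignored for the linear kernel.
#' @param degree polynomial degree.
#' @param coef0 offset term for sigmoid/polynomial kernels.
#' @rdname KernelSpec-class
#' @export
kernelSpec <- function(kind = c("radial", "linear", "sigmoid", "polynomial"),
                       gamma = 1, degree = 3, coef0 = 0) {
  kind <- match.arg(kind)
  new("KernelSpec", kind = kind, gamma = as.numeric(gamma),
      degree = as.numeric(degree), coef0 = as.numeric(coef0))
}

setMethod("show", "KernelSpec", function(object) {
  extra <- switch(object@kind,
    linear = "",
    radial = sprintf(" (gamma = %g)", object@gamma),
    sigmoid = sprintf(" (gamma = %g, coef0 = %g)", object@gamma, object@coef0),
    polynomial = sprintf(" (gamma = %g, degree = %d, coef0 = %g)",
                         object@gamma, as.integer(object@degree), object@coef0))
  cat("KernelSpec:", object@kind, extra, "\n", sep = "")
})

#' Fitted epsilon-insensitive support-vector regression model
#'
#' Stores the dual solution: the retained training rows (support vectors),
#' their signed dual coefficients \eqn{\alpha_i} (bounded by the cost `C`),
#' and the intercept `b`. Predictions are
#' \eqn{f(x) = \sum_i \alpha_i K(s_i, x) + b} and are deliberately not
#' clipped to [0, 1]: queen-side estimates above 1 are meaningful.
#'
#' @slot kernel a [KernelSpec-class].
#' @slot cost cost parameter C.
#' @slot epsilon tube half-width.
#' @slot supportVectors matrix of support-vector feature rows.
#' @slot dualCoefs signed dual coefficients, one per support vector.
#' @slot intercept scalar b.
#' @slot geneIds feature (gene) order of the model.
#' @slot scaler per-gene training standardization statistics (list with
#'   `center`, `scale`, `dropped`), or an empty list for pre-scaled input.
#' @export
setClass("SVRModel",
         representation(kernel = "KernelSpec", cost = "numeric",
                        epsilon = "numeric", supportVectors = "matrix",
                        dualCoefs = "numeric", intercept = "numeric",
                        geneIds = "character", scaler = "list"))

setValidity("SVRModel", function(object) {
  msg <- character()
  if (nrow(object@supportVectors) != length(object@dualCoefs))
    msg <- c(msg, "one dual coefficient per support vector required")
  if (nrow(object@supportVectors) > 0 &&
      ncol(object@supportVectors) != length(object@geneIds))
    msg <- c(msg, "support-vector columns must match geneIds")
  if (length(object@dualCoefs) &&
      any(abs(object@dualCoefs) > object@cost + 1e-8))
    msg <- c(msg, "|alpha| must not exceed the cost C")
  if (object@cost <= 0) msg <- c(msg, "cost must be positive")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SVRModel", function(object) {
  cat(sprintf("SVRModel: %s kernel, C = %g, epsilon = %g\n",
              object@kernel@kind, object@cost, object@epsilon))
  cat(sprintf("  %d support vectors over %d genes; intercept = %.4g\n",
              nrow(object@supportVectors), length(object@geneIds),
              object@intercept))
})

#' Repeated k-fold cross-validation summary
#'
#' @slot repeatErrors mean squared error over all held-out predictions, one
#'   value per repeat.
#' @slot meanError mean of `repeatErrors` (the validation error used for
#'   model comparison); its square root is also reported.
#' @slot k number of folds.
#' @slot repeats number of random re-binnings.
#' @slot seed seed that generated the partitions.
#' @export
setClass("CVResult",
         representation(repeatErrors = "numeric", meanError = "numeric",
                        k = "integer", repeats = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
  if (object@meanError < 0 ||
      abs(object@meanError - mean(object@repeatErrors)) > 1e-12)
    "meanError must equal the mean of nonnegative repeat errors" else TRUE
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold x %d repeats; MSE = %.5f (RMSE = %.5f)\n",
              object@k, object@repeats, object@meanError,
              sqrt(object@meanError)))
})

#' Grid-search result over (kernel, cost) combinations
#'
#' @slot grid data.frame of evaluated points (kind, gamma, degree, coef0,
#'   cost, cvError).
#' @slot selected index of the selected row (minimum CV error, ties broken by
#'   grid order).
#' @export
setClass("GridSearchResult",
         representation(grid = "data.frame", selected = "integer"))

setValidity("GridSearchResult", function(object) {
  if (nrow(object@grid) == 0) return("empty grid")
  err <- object@grid$cvError
  if (abs(err[object@selected] - min(err)) > 0)
    "selected point must attain the minimum CV error" else TRUE
})

setMethod("show", "GridSearchResult", function(object) {
  sel <- object@grid[object@selected, ]
  cat(sprintf("GridSearchResult: %d points; selected %s gamma=%g C=%g (MSE %.5f)\n",
              nrow(object@grid), sel$kind, sel$gamma, sel$cost, sel$cvError))
})

#' Recursive feature-elimination trace
#'
#' One row per iteration of the elimination loop: the gene-set size, the
#' repeated-CV mean squared error of the classifier on that set, and the gene
#' dropped afterwards (NA on the final iteration). `geneSets` holds the
#' strictly nested gene sets themselves.
#'
#' @slot iterations data.frame (iteration, n_genes, cv_error, dropped_gene).
#' @slot geneSets list of character vectors, one per iteration.
#' @slot config list recording (kernel, cost, epsilon, k, repeats, stop size,
#'   seed).
#' @export
setClass("RFETrace",
         representation(iterations = "data.frame", geneSets = "list",
                        config = "list"))

setValidity("RFETrace", function(object) {
  it <- object@iterations
  if (nrow(it) == 0) return("empty trace")
  if (nrow(it) != length(object@geneSets))
    return("one gene set per iteration required")
  sizes <- vapply(object@geneSets, length, 1L)
  if (!all(it$n_genes == sizes))
    return("n_genes must match gene-set sizes")
  if (nrow(it) > 1) {
    if (any(diff(sizes) >= 0L))
      return("gene-set size must strictly decrease between iterations")
    if ((object@config$batch %||% 1L) == 1L && any(diff(sizes) != -1L))
      return("gene-set size must decrease by exactly 1 per iteration")
    for (i in seq_len(nrow(it) - 1)) {
      if (!all(object@geneSets[[i + 1]] %in% object@geneSets[[i]]))
        return("gene sets must be strictly nested")
      if (!it$dropped_gene[i] %in% object@geneSets[[i]])
        return("dropped gene must belong to its iteration's gene set")
    }
  }
  TRUE
})

setMethod("show", "RFETrace", function(object) {
  it <- object@iterations
  cat(sprintf("RFETrace: %d iterations, %d -> %d genes; min CV MSE = %.5f at %d genes\n",
              nrow(it), it$n_genes[1], it$n_genes[nrow(it)],
              min(it$cv_error), it$n_genes[which.min(it$cv_error)]))
})

#' Optimal classifier selected from an RFE trace
#'
#' @slot model the [SVRModel-class] refit on all training samples restricted
#'   to the selected gene set.
#' @slot genes the selected caste-informative gene set.
#' @slot cvError the selected iteration's repeated-CV mean squared error.
#' @slot iteration index of the selected iteration in the trace.
#' @slot scaler training standardization statistics used by the pipeline.
#' @slot universe all genes surviving the expression filter (default overlap
#'   universe).
#' @slot normalization normalization metadata (pseudocount, per-sample
#'   depths).
#' @export
setClass("SelectedModel",
         representation(model = "SVRModel", genes = "character",
                        cvError = "numeric", iteration = "integer",
                        scaler = "list", universe = "character",
                        normalization = "list"))

setMethod("show", "SelectedModel", function(object) {
  cat(sprintf("SelectedModel: %d caste-informative genes; CV MSE = %.5f (iteration %d)\n",
              length(object@genes), object@cvError, object@iteration))
})

#' Gene-set overlap result
#'
#' @slot jaccard Jaccard index |A n B| / |A u B|.
#' @slot overlap overlap count.
#' @slot sizeA,sizeB set sizes.
#' @slot universe universe size.
#' @slot p one-sided hypergeometric upper-tail p-value P(X >= overlap).
#' @export
setClass("OverlapResult",
         representation(jaccard = "numeric", overlap = "integer",
                        sizeA = "integer", sizeB = "integer",
                        universe = "integer", p = "numeric"))

setValidity("OverlapResult", function(object) {
  if (object@jaccard < 0 || object@jaccard > 1) return("jaccard out of [0,1]")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0,1]")
  TRUE
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: |A|=%d |B|=%d overlap=%d of %d; Jaccard = %.3f, hypergeometric p = %.3g\n",
              object@sizeA, object@sizeB, object@overlap, object@universe,
              object@jaccard, object@p))
})

## ---- accessors ----

#' Accessors for fitted SVR models and selections
#'
#' @param object an [SVRModel-class], [SelectedModel-class], [CVResult-class]
#'   or [RFETrace-class] as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dualCoefs", function(object) standardGeneric("dualCoefs"))
#' @rdname accessors
#' @export
setMethod("dualCoefs", "SVRModel", function(object) object@dualCoefs)

#' @rdname accessors
#' @export
setGeneric("supportVectors", function(object) standardGeneric("supportVectors"))
#' @rdname accessors
#' @export
setMethod("supportVectors", "SVRModel", function(object) object@supportVectors)

#' @rdname accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))
#' @rdname accessors
#' @export
setMethod("intercept", "SVRModel", function(object) object@intercept)

#' @rdname accessors
#' @export
setGeneric("kernelOf", function(object) standardGeneric("kernelOf"))
#' @rdname accessors
#' @export
setMethod("kernelOf", "SVRModel", function(object) object@kernel)

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setMethod("modelGenes", "SVRModel", function(object) object@geneIds)
#' @rdname accessors
#' @export
setMethod("modelGenes", "SelectedModel", function(object) object@genes)

#' @rdname accessors
#' @export
setGeneric("cvError", function(object) standardGeneric("cvError"))
#' @rdname accessors
#' @export
setMethod("cvError", "CVResult", function(object) object@meanError)
#' @rdname accessors
#' @export
setMethod("cvError", "SelectedModel", function(object) object@cvError)

#' @rdname accessors
#' @export
setGeneric("traceTable", function(object) standardGeneric("traceTable"))
#' @rdname accessors
#' @export
setMethod("traceTable", "RFETrace", function(object) object@iterations)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "RFETrace", function(object) object@geneSets)

#' @rdname accessors
#' @export
setGeneric("selectedModel", function(object) standardGeneric("selectedModel"))
#' @rdname accessors
#' @export
setMethod("selectedModel", "SelectedModel", function(object) object@model)
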