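#' Fit an epsilon-insensitive support-vector regression model
#'
#' Caste labels are treated as a numeric response (worker = 0, queen = 1) and
#' fitted by \eqn{\epsilon}-SVR, so classifier estimates are continuous and
#' may legitimately fall outside [0, 1]. The dual problem is solved by the
#' libsvm SMO optimizer (via \pkg{e1071}, with feature scaling disabled:
#' standardization is this package's own explicit preprocessing step); the
#' returned object stores the dual solution so predictions can be recomputed
#' from first principles.
#'
#' @param x numeric feature matrix, samples as rows, genes as columns
#'   (colnames = gene identifiers). Must already be standardized.
#' @param y numeric response (0/1 caste coding for training).
#' @param spec a [KernelSpec-class]; default radial.
#' @param cost cost parameter C penalizing residuals outside the tube.
#' @param epsilon tube half-width (residuals smaller than this are not
#'   penalized).
#' @param tolerance SMO termination tolerance. The default is much tighter
#'   than libsvm's 1e-3 so the dual solution is reproducible to the accuracy
#'   the feature-weight ranking relies on; the fits here are small enough
#'   that this costs nothing.
#' @return an [SVRModel-class].
#' @export
fitSVR <- function(x, y, spec = kernelSpec("radial", gamma = 1 / ncol(x)),
                   cost = 2^5, epsilon = 0.1, tolerance = 1e-7) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in feature matrix")
  if (!all(is.finite(y))) stop("non-finite values in response")
  if (nrow(x) < 1) stop("at least 1 sample required")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  validObject(spec)
  genes <- colnames(x) %||% paste0("f", seq_len(ncol(x)))

  if (length(y) == 1 || var(y) == 0) {
    ## constant response: every sample sits inside the tube around mean(y),
    ## so the dual solution is all-zero with intercept y[1]
    return(new("SVRModel", kernel = spec, cost = cost, epsilon = epsilon,
               supportVectors = matrix(numeric(0), 0, ncol(x),
                                       dimnames = list(NULL, genes)),
               dualCoefs = numeric(0), intercept = y[1],
               geneIds = genes, scaler = list()))
  }

  fit <- e1071::svm(x = x, y = y, scale = FALSE, type = "eps-regression",
                    kernel = spec@kind,
                    gamma = if (spec@kind == "linear") 1 else spec@gamma,
                    degree = spec@degree, coef0 = spec@coef0,
                    cost = cost, epsilon = epsilon, tolerance = tolerance)
  sv <- as.matrix(fit$SV)
  colnames(sv) <- genes
  new("SVRModel", kernel = spec, cost = cost, epsilon = epsilon,
      supportVectors = sv, dualCoefs = as.numeric(fit$coefs),
      intercept = -fit$rho, geneIds = genes, scaler = list())
}

#' Predict classifier estimates from a fitted SVR model
#'
#' Evaluates the dual form
#' \eqn{f(x) = \sum_i \alpha_i K(s_i, x) + b} directly from the stored
#' support vectors and dual coefficients. Estimates are not clipped: values
#' slightly above 1 (queen-like) or below 0 (worker-like) are expected.
#'
#' @param model an [SVRModel-class].
#' @param x query matrix with columns exactly matching `modelGenes(model)`,
#'   standardized by the same scaler as the training data.
#' @return numeric vector of estimates, one per query row.
#' @export
predictSVR <- function(model, x) {
  stopifnot(is(model, "SVRModel"))
  x <- as.matrix(x)
  if (ncol(x) != length(model@geneIds))
    stop("query has ", ncol(x), " features; model expects ",
         length(model@geneIds))
  if (!is.null(colnames(x)) && !identical(colnames(x), model@geneIds)) {
    if (!all(model@geneIds %in% colnames(x)))
      stop("model genes absent from query: ",
           paste(setdiff(model@geneIds, colnames(x)), collapse = ", "))
    x <- x[, model@geneIds, drop = FALSE]
  }
  if (nrow(model@supportVectors) == 0)
    return(rep(model@intercept, nrow(x)))
  K <- kernelMatrix_(model@kernel, x, model@supportVectors)
  as.numeric(K %*% model@dualCoefs + model@intercept)
}

#' @rdname predictSVR
#' @param object an [SVRModel-class].
#' @param newdata query feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, ...) {
  predictSVR(object, newdata)
})

#' Per-gene feature weights of a fitted classifier
#'
#' The weight of gene g is the matrix product of the dual coefficients with
#' the support vectors, \eqn{w_g = \sum_i \alpha_i s_{i,g}}. For a linear
#' kernel this is the primal weight vector (the gradient of the decision
#' function); under nonlinear kernels it is the same linear-primal heuristic
#' the elimination loop ranks genes by.
#'
#' @param model an [SVRModel-class].
#' @return named numeric vector, one weight per model gene.
#' @export
featureWeights <- function(model) {
  stopifnot(is(model, "SVRModel"))
  w <- if (nrow(model@supportVectors) == 0)
    numeric(length(model@geneIds))
  else as.numeric(crossprod(model@dualCoefs, model@supportVectors))
  names(w) <- model@geneIds
  w
}

#' Serialize / restore an SVR model as JSON
#'
#' Writes the complete dual solution (kernel spec, C, epsilon, support
#' vectors, dual coefficients, intercept, gene order, scaler and
#' normalization metadata) with 17 significant digits so the round-trip is
#' bit-exact.
#'
#' @param model an [SVRModel-class].
#' @param path output (input) file path.
#' @return `readSVRModel` returns the restored [SVRModel-class].
#' @export
writeSVRModel <- function(model, path) {
  stopifnot(is(model, "SVRModel"))
  obj <- list(
    kernel = list(kind = model@kernel@kind, gamma = model@kernel@gamma,
                  degree = model@kernel@degree, coef0 = model@kernel@coef0),
    cost = model@cost, epsilon = model@epsilon,
    support_vectors = unname(model@supportVectors),
    dual_coefs = model@dualCoefs, intercept = model@intercept,
    gene_ids = model@geneIds, scaler = model@scaler)
  writeLines(jsonlite::toJSON(obj, digits = 17, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname writeSVRModel
#' @export
readSVRModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  k <- obj$kernel
  spec <- new("KernelSpec", kind = k$kind, gamma = as.numeric(k$gamma),
              degree = as.numeric(k$degree), coef0 = as.numeric(k$coef0))
  sv <- obj$support_vectors
  genes <- as.character(obj$gene_ids)
  sv <- if (is.null(sv) || length(sv) == 0)
    matrix(numeric(0), 0, length(genes)) else as.matrix(sv)
  colnames(sv) <- genes
  scaler <- obj$scaler
  if (length(scaler)) scaler <- lapply(scaler, function(z)
    if (is.list(z)) z else z)
  new("SVRModel", kernel = spec, cost = as.numeric(obj$cost),
      epsilon = as.numeric(obj$epsilon), supportVectors = sv,
      dualCoefs = as.numeric(obj$dual_coefs),
      intercept = as.numeric(obj$intercept), geneIds = genes,
      scaler = if (length(scaler)) scaler else list())
}
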