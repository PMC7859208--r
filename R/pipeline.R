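#' Train the caste classifier on queen and control-worker transcriptomes
#'
#' Composes the full training path: expression filter (>20 counts in at
#' least one experimental group, applied over all groups present), log2-CPM
#' normalization, per-gene standardization on the training samples, an
#' optional kernel/cost grid search, recursive feature elimination with
#' repeated threefold cross-validation, and minimum-error model selection.
#' Caste labels are coded worker = 0, queen = 1.
#'
#' @param counts count matrix (genes x samples) or [CasteExperiment-class];
#'   all experimental groups should be present so the expression filter sees
#'   the full design.
#' @param samples sample metadata (ignored for a CasteExperiment).
#' @param spec a [KernelSpec-class], or `NULL` for a radial kernel with
#'   gamma = 1/p (p = number of standardized genes).
#' @param cost,epsilon SVR hyperparameters.
#' @param k,repeats cross-validation folds and repeats.
#' @param stopSize gene count at which elimination stops.
#' @param grid optional grid from [svrGrid()]; when supplied, the grid-search
#'   winner overrides `spec`/`cost`.
#' @param filterThreshold expression-filter count threshold.
#' @param pseudocount log2-CPM pseudocount.
#' @param seed master seed for all cross-validation binning.
#' @param verbose log one line per elimination iteration.
#' @return a [SelectedModel-class] carrying the selected gene set, the refit
#'   model, its CV error, the training scaler, the post-filter gene universe
#'   and normalization metadata. The RFE trace is attached as attribute
#'   `trace`.
#' @export
trainCasteClassifier <- function(counts, samples = NULL, spec = NULL,
                                 cost = 2^5, epsilon = 0.1, k = 3,
                                 repeats = 20, stopSize = 100, grid = NULL,
                                 filterThreshold = 20, pseudocount = 1,
                                 seed = 1, verbose = FALSE) {
  rc <- resolveCounts_(counts, samples)
  for (g in c("queen", "control_worker"))
    if (!any(rc$samples$group == g)) stop("missing training group: ", g)

  filtered <- suppressWarnings(
    filterLowCounts(rc$counts, rc$samples, threshold = filterThreshold))
  train <- which(rc$samples$group %in% c("queen", "control_worker"))
  expr <- normalizeLogCPM(filtered[, train, drop = FALSE],
                          pseudocount = pseudocount)
  std <- standardizeFeatures(expr)
  x <- std$x
  y <- as.numeric(rc$samples$group[train] == "queen")
  rownames(x) <- rc$samples$sample_id[train]

  n <- nrow(x)
  if (k > n) {
    warning("k = ", k, " exceeds ", n, " training samples; using ", n,
            "-fold cross-validation")
    k <- n
  }

  if (!is.null(grid)) {
    gs <- gridSearch(x, y, grid, k = k, repeats = repeats,
                     seed = seedStream(seed, 1e6), epsilon = epsilon)
    pt <- selectedPoint(gs)
    spec <- pt$spec; cost <- pt$cost
  } else if (is.null(spec)) {
    spec <- kernelSpec("radial", gamma = 1 / ncol(x))
  }

  trace <- runRFE(x, y, spec, cost = cost, epsilon = epsilon, k = k,
                  repeats = repeats, stopSize = stopSize, seed = seed,
                  verbose = verbose)
  sel <- selectOptimal(trace, x, y)
  sel@scaler <- std$scaler
  sel@universe <- rownames(filtered)
  sel@normalization <- attr(expr, "normalization")[c("formula", "pseudocount")]
  attr(sel, "trace") <- trace
  sel
}

#' Classifier estimates for query samples
#'
#' Normalizes query counts to log2-CPM over the model's gene universe,
#' standardizes them with the TRAINING statistics only, and evaluates the
#' selected classifier. Estimates are unclipped.
#'
#' @param sel a [SelectedModel-class] from [trainCasteClassifier()].
#' @param counts count matrix or [CasteExperiment-class] containing the
#'   query samples.
#' @param samples sample metadata (ignored for a CasteExperiment).
#' @param groups group labels to classify (default: all present).
#' @return a `ClassificationReport`: list with `estimates` (data.frame
#'   sample_id, group, estimate) and `groups` (per-group mean, sd, min, max,
#'   n).
#' @export
classifySamples <- function(sel, counts, samples = NULL, groups = NULL) {
  stopifnot(is(sel, "SelectedModel"))
  rc <- resolveCounts_(counts, samples)
  groups <- groups %||% unique(as.character(rc$samples$group))
  idx <- which(rc$samples$group %in% groups)
  if (length(idx) == 0) stop("no samples in requested groups")
  missing <- setdiff(sel@universe, rownames(rc$counts))
  if (length(missing))
    stop("model universe genes absent from query counts: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  cts <- rc$counts[sel@universe, idx, drop = FALSE]
  expr <- normalizeLogCPM(cts, pseudocount = sel@normalization$pseudocount %||% 1)
  scaler <- list(center = sel@scaler$center[sel@genes],
                 scale = sel@scaler$scale[sel@genes])
  z <- applyStandardize(scaler, expr)
  est <- predictSVR(sel@model, z)
  estimates <- data.frame(sample_id = rc$samples$sample_id[idx],
                          group = as.character(rc$samples$group[idx]),
                          estimate = est, stringsAsFactors = FALSE)
  report <- list(estimates = estimates,
                 groups = groupSummaries(estimates))
  class(report) <- "ClassificationReport"
  report
}

groupSummaries <- function(estimates) {
  sp <- split(estimates$estimate, estimates$group)
  out <- data.frame(group = names(sp),
                    n = vapply(sp, length, 1L),
                    mean = vapply(sp, mean, 1),
                    sd = vapply(sp, sd, 1),
                    min = vapply(sp, min, 1),
                    max = vapply(sp, max, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(match(out$group, casteGroups())), , drop = FALSE]
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat("ClassificationReport:", nrow(x$estimates), "samples\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Compare classifier estimates between the two queen-removal timepoints
#'
#' Two-sided Wilcoxon rank-sum test of day-3 vs day-12 post-removal
#' estimates, with group means and standard deviations.
#'
#' @param report a `ClassificationReport` containing qr_day3 and qr_day12
#'   samples.
#' @return list: W, p, method, and per-group n/mean/sd.
#' @export
compareQRTimepoints <- function(report) {
  est <- report$estimates
  x <- est$estimate[est$group == "qr_day3"]
  y <- est$estimate[est$group == "qr_day12"]
  if (length(x) == 0 || length(y) == 0)
    stop("both qr_day3 and qr_day12 samples are required")
  wt <- wilcoxonRankSum(x, y)
  list(W = wt$W, p = wt$p, method = wt$method,
       qr_day3 = list(n = length(x), mean = mean(x), sd = sd(x)),
       qr_day12 = list(n = length(y), mean = mean(y), sd = sd(y)))
}

#' Linear models linking classifier estimates to phenotype
#'
#' Fits, separately for each predictor, an ordinary least squares regression
#' of the classifier estimate on phenotypic queenness, ovarian index,
#' dominance and age, plus the age-residualized variants (estimate on the
#' residuals of each phenotype regressed on age), reporting slope, standard
#' error, two-sided p and Pearson correlation. Zero-variance predictors are
#' flagged rather than fitted.
#'
#' @param report a `ClassificationReport` for the samples to model
#'   (typically the queen-removal individuals).
#' @param samples sample metadata providing the phenotype columns.
#' @param groups sample groups to include (default: the two QR groups).
#' @return data.frame (predictor, n, slope, se, p, r, note).
#' @export
fitPhenotypeModels <- function(report, samples,
                               groups = c("qr_day3", "qr_day12")) {
  est <- report$estimates
  est <- est[est$group %in% groups, , drop = FALSE]
  m <- merge(est, samples, by = "sample_id", sort = FALSE)
  plain <- c(queenness = "queenness", ovarian_index = "ovarian_index",
             dominance = "dominance", age = "age")
  resids <- c(queenness_resid_age = "queenness",
              ovarian_resid_age = "ovarian_index",
              dominance_resid_age = "dominance")
  rows <- list()
  addRow <- function(name, xvec) {
    ok <- is.finite(xvec) & is.finite(m$estimate)
    ## sd relative to the variable's scale: numerically-zero residual
    ## vectors count as zero-variance
    tol <- 1e-10 * max(1, abs(xvec[ok]))
    if (sum(ok) >= 3 && sd(xvec[ok]) > tol) {
      f <- olsFit(m$estimate[ok], xvec[ok])
      rows[[name]] <<- data.frame(predictor = name, n = f$n, slope = f$slope,
                                  se = f$se, p = f$p, r = f$r, note = "",
                                  stringsAsFactors = FALSE)
    } else {
      rows[[name]] <<- data.frame(predictor = name, n = sum(ok),
                                  slope = NA_real_, se = NA_real_,
                                  p = NA_real_, r = NA_real_,
                                  note = "zero-variance or insufficient data",
                                  stringsAsFactors = FALSE)
    }
  }
  for (nm in names(plain)) addRow(nm, m[[plain[nm]]])
  for (nm in names(resids)) {
    ph <- m[[resids[nm]]]
    ok <- is.finite(ph) & is.finite(m$age)
    if (sum(ok) >= 3 && sd(m$age[ok]) > 0 && sd(ph[ok]) > 0) {
      rv <- rep(NA_real_, nrow(m))
      rv[ok] <- residualsOn(ph[ok], m$age[ok])
      addRow(nm, rv)
    } else addRow(nm, rep(0, nrow(m)))  # degenerate -> flagged
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenotypic queenness from ovarian development and dominance
#'
#' Fits a maximum-likelihood logistic regression of caste (worker = 0,
#' queen = 1) on ovarian index and dominance over the training groups, then
#' scores ALL samples (including queen-removal individuals) with the fitted
#' probability. Predictors are standardized internally using training
#' statistics. With `lambda = 0` and completely separable training data, a
#' warning is raised and a minimal ridge penalty (1e-4, on the standardized
#' coefficients, intercept unpenalized) is applied automatically so the
#' score stays calibrated.
#'
#' @param samples sample metadata with `ovarian_index` and `dominance`.
#' @param trainGroups the two training group labels (first = coded 0,
#'   second = coded 1).
#' @param lambda ridge penalty (default 0 = plain maximum likelihood).
#' @return `samples` with the `queenness` column filled.
#' @export
phenotypeQueenness <- function(samples,
                               trainGroups = c("control_worker", "queen"),
                               lambda = 0) {
  for (g in trainGroups)
    if (!any(samples$group == g)) stop("missing training group: ", g)
  tr <- samples$group %in% trainGroups
  y <- as.numeric(samples$group[tr] == trainGroups[2])
  ctr <- c(ovarian_index = mean(samples$ovarian_index[tr]),
           dominance = mean(samples$dominance[tr]))
  scl <- c(ovarian_index = sd(samples$ovarian_index[tr]),
           dominance = sd(samples$dominance[tr]))
  scl[scl == 0] <- 1
  Z <- cbind(1,
             (samples$ovarian_index - ctr[1]) / scl[1],
             (samples$dominance - ctr[2]) / scl[2])
  Ztr <- Z[tr, , drop = FALSE]

  beta <- NULL
  if (lambda == 0) {
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ Ztr[, 2] + Ztr[, 3], family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    ## complete separation also shows up as unbounded/aliased coefficients
    ## or degenerate fitted probabilities
    pr <- fitted(fit)
    if (any(is.na(coef(fit))) || max(abs(coef(fit)), na.rm = TRUE) > 1e3 ||
        all(pmin(pr, 1 - pr) < 1e-6))
      separated <- TRUE
    if (separated) {
      warning("complete separation in queenness model; applying minimal ",
              "ridge penalty (lambda = 1e-4)")
      lambda <- 1e-4
    } else beta <- unname(coef(fit))
  }
  if (is.null(beta)) beta <- ridgeLogistic_(Ztr, y, lambda)
  samples$queenness <- as.numeric(stats::plogis(Z %*% beta))
  samples
}

## Newton-Raphson for ridge-penalized logistic regression; the intercept is
## unpenalized. Base R has no fixed-lambda penalized binomial fit.
ridgeLogistic_ <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  D <- diag(c(0, rep(1, p - 1)), p)
  beta <- numeric(p)
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - 2 * lambda * D %*% beta
    H <- crossprod(X, X * W) + 2 * lambda * D
    step <- solve(H + diag(1e-12, p), g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Overlap between the selected gene set and another gene set
#'
#' Jaccard index and one-sided hypergeometric overlap test; the universe
#' defaults to the model's post-filter gene universe.
#'
#' @param svmSet gene set selected by feature elimination (character vector
#'   or [SelectedModel-class]).
#' @param other the comparison gene set.
#' @param universe background set; defaults to the SelectedModel's universe.
#' @return an [OverlapResult-class].
#' @export
compareGeneSets <- function(svmSet, other, universe = NULL) {
  if (is(svmSet, "SelectedModel")) {
    universe <- universe %||% svmSet@universe
    svmSet <- svmSet@genes
  }
  if (is.null(universe)) stop("a gene universe is required")
  overlapResult(svmSet, other, universe)
}
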