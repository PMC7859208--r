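## Partition n samples into k as-even-as-possible bins after a seeded shuffle
## of the canonical order. Returns a list of index vectors.
cvPartition <- function(n, k, seed) {
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Repeated k-fold cross-validation error of an SVR configuration
#'
#' For each repeat, samples are randomly partitioned into `k` bins (threefold
#' by default, matching how the classifiers are assessed); each bin is
#' predicted by a model trained on the remaining bins, and the repeat's error
#' is the mean squared error over all held-out predictions. The reported
#' validation error is the mean over repeats.
#'
#' The partition is drawn from sample positions in a canonical order: when
#' `x` has rownames, the canonical order is the sorted rownames, which makes
#' the result invariant to row shuffling of the input.
#'
#' @inheritParams fitSVR
#' @param k number of folds (default 3).
#' @param repeats number of random re-binnings (default 20).
#' @param seed integer seed for the bin assignments.
#' @return a [CVResult-class].
#' @export
crossValidationError <- function(x, y, spec, cost = 2^5, epsilon = 0.1,
                                 k = 3, repeats = 20, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  if (k < 2) stop("k must be at least 2")
  if (repeats < 1) stop("repeats must be at least 1")
  ord <- if (!is.null(rownames(x))) order(rownames(x)) else seq_len(n)
  repeatErrors <- numeric(repeats)
  for (r in seq_len(repeats)) {
    bins <- cvPartition(n, k, seedStream(seed, r))
    sq <- numeric(0)
    for (bin in bins) {
      hold <- ord[bin]
      train <- setdiff(seq_len(n), hold)
      fit <- fitSVR(x[train, , drop = FALSE], y[train], spec, cost, epsilon)
      pred <- predictSVR(fit, x[hold, , drop = FALSE])
      sq <- c(sq, (pred - y[hold])^2)
    }
    repeatErrors[r] <- mean(sq)
  }
  new("CVResult", repeatErrors = repeatErrors,
      meanError = mean(repeatErrors), k = as.integer(k),
      repeats = as.integer(repeats), seed = as.integer(seed))
}

#' Build a kernel/cost search grid
#'
#' `svrGrid` crosses kernel specifications with cost values (kernel-major,
#' then gamma ascending, then cost ascending — the order that also breaks
#' grid-search ties). `refinedGrid` is the focused radial-kernel search used
#' once the radial kernel has won the broad comparison: 5 log2-spaced cost
#' values strictly inside (2^4, 2^6) and 5 log10-spaced gamma values strictly
#' inside (1e-7, 1e-5), centred on the operating point gamma = 1e-6,
#' C = 2^5.
#'
#' @param kinds kernel kinds to include.
#' @param gammas gamma values (ignored for the linear kernel).
#' @param costs cost values.
#' @param degree,coef0 passed to [kernelSpec()].
#' @return a list of `list(spec = KernelSpec, cost = numeric)` grid points.
#' @export
svrGrid <- function(kinds = "radial", gammas = 1e-6, costs = 2^5,
                    degree = 3, coef0 = 0) {
  grid <- list()
  for (kind in kinds) {
    gs <- if (kind == "linear") NA_real_ else sort(gammas)
    for (g in gs) for (cc in sort(costs)) {
      spec <- if (kind == "linear") kernelSpec("linear")
        else kernelSpec(kind, gamma = g, degree = degree, coef0 = coef0)
      grid[[length(grid) + 1L]] <- list(spec = spec, cost = cc)
    }
  }
  grid
}

#' @rdname svrGrid
#' @export
refinedGrid <- function() {
  svrGrid(kinds = "radial",
          gammas = 10^seq(-7, -5, length.out = 7)[2:6],
          costs = 2^seq(4, 6, length.out = 7)[2:6])
}

#' Grid search over kernel/cost combinations
#'
#' Evaluates [crossValidationError()] at every grid point with a shared seed
#' (so every point sees the same bin assignments) and selects the point with
#' the minimum mean validation error; ties are broken by grid order (first
#' wins).
#'
#' @inheritParams crossValidationError
#' @param grid a list of grid points from [svrGrid()].
#' @return a [GridSearchResult-class].
#' @export
gridSearch <- function(x, y, grid, k = 3, repeats = 20, seed = 1,
                       epsilon = 0.1) {
  if (length(grid) == 0) stop("empty grid")
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pt <- grid[[i]]
    cv <- crossValidationError(x, y, pt$spec, cost = pt$cost,
                               epsilon = epsilon, k = k, repeats = repeats,
                               seed = seed)
    rows[[i]] <- data.frame(kind = pt$spec@kind,
                            gamma = if (pt$spec@kind == "linear") NA_real_
                                    else pt$spec@gamma,
                            degree = pt$spec@degree, coef0 = pt$spec@coef0,
                            cost = pt$cost, cvError = cv@meanError)
  }
  tab <- do.call(rbind, rows)
  new("GridSearchResult", grid = tab, selected = which.min(tab$cvError))
}

#' Kernel spec and cost of the selected grid point
#'
#' @param gs a [GridSearchResult-class].
#' @return `list(spec = KernelSpec, cost = numeric)`.
#' @export
selectedPoint <- function(gs) {
  stopifnot(is(gs, "GridSearchResult"))
  row <- gs@grid[gs@selected, ]
  spec <- if (row$kind == "linear") kernelSpec("linear")
    else kernelSpec(row$kind, gamma = row$gamma, degree = row$degree,
                    coef0 = row$coef0)
  list(spec = spec, cost = row$cost)
}
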