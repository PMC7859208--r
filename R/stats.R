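#' Jaccard index of two gene sets
#'
#' |A n B| / |A u B|; defined as 0 when both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return scalar in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' One-sided hypergeometric overlap test
#'
#' Upper-tail probability P(X >= |A n B|) where X is hypergeometric with
#' universe size N = |universe|, K = |A| marked elements and n = |B| draws.
#' Symmetric in A and B.
#'
#' @param a,b gene sets, both subsets of `universe`.
#' @param universe the background gene set.
#' @return p-value in (0, 1].
#' @export
hypergeomOverlapTest <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe))
    stop("set A not contained in universe: ",
         paste(utils::head(setdiff(a, universe), 5), collapse = ", "))
  if (!all(b %in% universe))
    stop("set B not contained in universe: ",
         paste(utils::head(setdiff(b, universe), 5), collapse = ", "))
  q <- length(intersect(a, b))
  phyper(q - 1, length(a), length(universe) - length(a), length(b),
         lower.tail = FALSE)
}

#' Overlap of two gene sets (Jaccard + hypergeometric)
#'
#' @inheritParams hypergeomOverlapTest
#' @return an [OverlapResult-class].
#' @export
overlapResult <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  p <- hypergeomOverlapTest(a, b, universe)
  new("OverlapResult", jaccard = jaccardIndex(a, b),
      overlap = length(intersect(a, b)), sizeA = length(a),
      sizeB = length(b), universe = length(unique(universe)), p = p)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic W is the Mann-Whitney U of the first sample: the number of
#' pairs (x_i, y_j) with x_i > y_j, ties counting 1/2 (computed from
#' mid-ranks). This is the convention under which two-group rank tests are
#' conventionally reported as "W". The two-sided p-value is exact (from the
#' null Wilcoxon distribution) when there are no ties and
#' n_x * n_y <= 400; otherwise a normal approximation with tie and
#' continuity corrections is used. The regime is reported in `method`.
#'
#' @param x,y numeric samples (both nonempty).
#' @return list with `W`, `p`, `method` ("exact" or "normal"), and the group
#'   sizes.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx * ny <= 400) {
    p <- if (W > nx * ny / 2)
      pwilcox(W - 1, nx, ny, lower.tail = FALSE) else pwilcox(W, nx, ny)
    p <- min(2 * p, 1)
    method <- "exact"
  } else {
    z <- W - nx * ny / 2
    tieTab <- table(r)
    n <- nx + ny
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "normal"
  }
  list(W = W, p = p, method = method, n_x = nx, n_y = ny)
}

#' Simple linear regression with intercept
#'
#' Ordinary least squares of `y` on `x`; the slope standard error uses the
#' residual variance on n - 2 degrees of freedom and the two-sided p-value
#' comes from the t distribution. The Pearson correlation of (x, y) is
#' included, matching how the phenotype-model scatterplots are annotated.
#'
#' @param y response vector.
#' @param x predictor vector (non-constant, length >= 3).
#' @return list with `slope`, `intercept`, `se`, `p`, `r`, `residuals`, `n`.
#' @export
olsFit <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete observations required")
  if (sd(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  ## summary.lm warns on numerically perfect fits; the SE/p of 0 it returns
  ## are exactly what the caller expects there
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       se = unname(sm[2, 2]), p = unname(sm[2, 4]), r = cor(x, y),
       residuals = unname(resid(fit)), n = length(x))
}

#' Residuals of y regressed on x
#'
#' @inheritParams olsFit
#' @return residual vector (mean 0).
#' @export
residualsOn <- function(y, x) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (sd(x) == 0) stop("constant predictor")
  unname(resid(lm(y ~ x)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up procedure with enforced monotonicity (adjusted values lie
#' in [p_i, 1]).
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
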