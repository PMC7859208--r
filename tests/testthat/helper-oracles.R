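# Independent oracles used to validate the implementation. Each is written
# from first principles and shares no code path with the package internals.

# Kernel evaluated longhand (no vectorized shortcuts).
oracleKernel <- function(kind, gamma, degree, coef0, x, y) {
  switch(kind,
    radial = exp(-gamma * sum((x - y)^2)),
    linear = sum(x * y),
    sigmoid = tanh(gamma * sum(x * y) + coef0),
    polynomial = (gamma * sum(x * y) + coef0)^degree)
}

# Brute-force quadratic-programming solution of the epsilon-SVR dual:
# interior-point solve (kernlab::ipop) followed by an exact KKT polish on
# the identified active set. Returns a prediction function.
oracleSVR <- function(x, y, kind = "radial", gamma = 1, C = 10, eps = 0.1,
                      degree = 3, coef0 = 0) {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- oracleKernel(kind, gamma, degree, coef0, x[i, ], x[j, ])
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * n)
  sol <- kernlab::ipop(c(eps - y, eps + y), H,
                       matrix(c(rep(1, n), rep(-1, n)), 1), b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 9, maxiter = 300)
  u <- kernlab::primal(sol)
  a <- u[seq_len(n)]; as <- u[n + seq_len(n)]
  beta <- a - as
  tol <- 1e-4 * C
  free <- which((a > tol & a < C - tol) | (as > tol & as < C - tol))
  sgn <- ifelse(a > as, -1, +1)  # tube side: -eps (alpha) / +eps (alpha*)
  bound <- setdiff(seq_len(n), free)
  betaB <- ifelse(abs(beta[bound]) > C - tol, sign(beta[bound]) * C, 0)
  stopifnot(length(free) > 0)  # fixtures are chosen generic
  M <- rbind(cbind(K[free, free, drop = FALSE], 1),
             c(rep(1, length(free)), 0))
  rhs <- c(y[free] + sgn[free] * eps -
             (if (length(bound)) K[free, bound, drop = FALSE] %*% betaB else 0),
           -sum(betaB))
  solv <- solve(M, rhs)
  betaP <- numeric(n)
  betaP[bound] <- betaB
  betaP[free] <- solv[seq_along(free)]
  b <- solv[length(free) + 1]
  function(xq) {
    apply(as.matrix(xq), 1, function(q)
      sum(betaP * vapply(seq_len(n), function(i)
        oracleKernel(kind, gamma, degree, coef0, x[i, ], q), 0)) + b)
  }
}

# Exhaustive hypergeometric upper tail: enumerate every draw of size n from
# a universe of size N whose first K elements are marked, and count draws
# with overlap >= q.
oracleHyperTail <- function(N, K, n, q) {
  if (n == 0) return(as.numeric(q <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= q)
}

# Exact two-sided rank-sum p by full enumeration of label assignments.
oracleWilcoxP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  Wobs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  assigns <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  Ws <- apply(assigns, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-9)
}

# Iteratively reweighted least squares for unpenalized logistic regression.
oracleIRLS <- function(X, y, maxit = 200, tol = 1e-12) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-as.numeric(X %*% beta)))
    W <- pmax(p * (1 - p), 1e-12)
    z <- X %*% beta + (y - p) / W
    betaNew <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(betaNew - beta)) < tol) break
    beta <- as.numeric(betaNew)
  }
  beta
}

# Closed-form simple linear regression via the normal equations, with the
# t-based slope inference worked longhand.
oracleOLS <- function(y, x) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(-abs(tstat), n - 2))
}
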