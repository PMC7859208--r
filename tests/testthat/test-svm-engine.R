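test_that("kernel values match their closed forms and are symmetric", {
  expect_equal(kernelValue(kernelSpec("radial", gamma = 2), c(1, 2), c(1, 2)), 1)
  expect_equal(kernelValue(kernelSpec("radial", gamma = 0.5), c(1, 0), c(0, 0)),
               exp(-0.5))
  expect_equal(kernelValue(kernelSpec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernelValue(kernelSpec("sigmoid", gamma = 0.1, coef0 = 0.2),
                           c(1, 2), c(3, 4)), tanh(0.1 * 11 + 0.2))
  expect_equal(kernelValue(kernelSpec("polynomial", gamma = 0.5, degree = 2,
                                      coef0 = 1), c(1, 2), c(3, 4)),
               (0.5 * 11 + 1)^2)
  expect_error(kernelValue(kernelSpec("radial"), c(1, 2), c(1, 2, 3)), "length")

  set.seed(11)
  for (kind in c("radial", "linear", "sigmoid", "polynomial")) {
    spec <- kernelSpec(kind, gamma = 0.3, degree = 2, coef0 = 0.5)
    for (i in 1:20) {
      x <- rnorm(6); y <- rnorm(6)
      expect_equal(kernelValue(spec, x, y), kernelValue(spec, y, x))
      expect_equal(kernelValue(spec, x, y),
                   oracleKernel(kind, 0.3, 2, 0.5, x, y))
      if (kind == "radial") {
        v <- kernelValue(spec, x, y)
        expect_true(v > 0 && v <= 1)
      }
    }
  }
})

test_that("constant responses give a degenerate model predicting the constant", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fitSVR(x, rep(0.7, 5), kernelSpec("radial", gamma = 1), cost = 10)
  expect_identical(nrow(supportVectors(fit)), 0L)
  expect_equal(predictSVR(fit, x), rep(0.7, 5))
  expect_equal(featureWeights(fit), c(a = 0, b = 0, c = 0))
})

test_that("symmetric two-point problem predicts the midpoint at the centre", {
  x <- matrix(c(-1, 1), 2, 1)
  fit <- fitSVR(x, c(0, 1), kernelSpec("radial", gamma = 1), cost = 10,
                epsilon = 0.01)
  expect_equal(predictSVR(fit, matrix(0, 1, 1)), 0.5, tolerance = 1e-6)
})

test_that("fitted models satisfy dual-form invariants", {
  tt <- tinyTrainingSet(seed = 3)
  fit <- fitSVR(tt$x, tt$y, kernelSpec("radial", gamma = 1 / 40), cost = 5)
  expect_true(all(abs(dualCoefs(fit)) <= 5 + 1e-8))
  expect_identical(length(dualCoefs(fit)), nrow(supportVectors(fit)))
  ## duplicated query rows get identical estimates
  q <- tt$x[c(1, 1, 2), ]
  p <- predictSVR(fit, q)
  expect_identical(p[1], p[2])
  ## interpolation with large C and tiny epsilon
  fit2 <- fitSVR(tt$x, tt$y, kernelSpec("radial", gamma = 1 / 10),
                 cost = 1e4, epsilon = 1e-4)
  expect_lt(max(abs(predictSVR(fit2, tt$x) - tt$y)), 1e-4 + 1e-3)
})

test_that("hand-built models evaluate the dual sum as written", {
  sv <- matrix(c(1, 2, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("gA", "gB")))
  m <- new("SVRModel", kernel = kernelSpec("radial", gamma = 1), cost = 1,
           epsilon = 0.1, supportVectors = sv, dualCoefs = c(0.5, -0.25),
           intercept = 0.1, geneIds = c("gA", "gB"), scaler = list())
  q <- c(1, 1)
  manual <- 0.5 * exp(-sum((c(1, 2) - q)^2)) -
    0.25 * exp(-sum((c(0, 1) - q)^2)) + 0.1
  expect_equal(predictSVR(m, matrix(q, 1, 2)), manual)
  ## all-zero alpha predicts the intercept everywhere
  m0 <- new("SVRModel", kernel = kernelSpec("linear"), cost = 1,
            epsilon = 0.1, supportVectors = sv, dualCoefs = c(0, 0),
            intercept = 0.3, geneIds = c("gA", "gB"), scaler = list())
  expect_equal(predictSVR(m0, matrix(rnorm(6), 3, 2)), rep(0.3, 3))
})

test_that("feature weights are the coefficient-support-vector matrix product", {
  sv <- matrix(c(1, 2, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("gA", "gB")))
  m <- new("SVRModel", kernel = kernelSpec("linear"), cost = 2, epsilon = 0.1,
           supportVectors = sv, dualCoefs = c(1, -1), intercept = 0,
           geneIds = c("gA", "gB"), scaler = list())
  expect_equal(featureWeights(m), c(gA = 1, gB = 1))

  ## linear kernel: weights equal the finite-difference gradient
  tt <- tinyTrainingSet(seed = 4, nGenes = 10, nInf = 3)
  fit <- fitSVR(tt$x, tt$y, kernelSpec("linear"), cost = 2)
  w <- featureWeights(fit)
  x0 <- tt$x[1, , drop = FALSE]
  h <- 1e-5
  fd <- vapply(seq_len(ncol(tt$x)), function(j) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    (predictSVR(fit, xp) - predictSVR(fit, xm)) / (2 * h)
  }, 0)
  expect_equal(unname(w), fd, tolerance = 1e-4)
})

test_that("dual-form predictions agree with the fitting library's own", {
  tt <- tinyTrainingSet(seed = 5)
  for (kind in c("radial", "linear", "sigmoid", "polynomial")) {
    spec <- kernelSpec(kind, gamma = 0.02, degree = 2, coef0 = 0.1)
    fit <- fitSVR(tt$x, tt$y, spec, cost = 4)
    ref <- e1071::svm(x = tt$x, y = tt$y, scale = FALSE,
                      type = "eps-regression", kernel = kind,
                      gamma = if (kind == "linear") 1 else 0.02, degree = 2,
                      coef0 = 0.1, cost = 4, epsilon = 0.1,
                      tolerance = 1e-7)
    expect_equal(predictSVR(fit, tt$x), unname(predict(ref, tt$x)),
                 tolerance = 1e-10)
  }
})

test_that("model serialization round-trips bit-exactly through JSON", {
  tt <- tinyTrainingSet(seed = 6)
  fit <- fitSVR(tt$x, tt$y, kernelSpec("radial", gamma = 1 / 40), cost = 32)
  fit@scaler <- list(center = stats::setNames(rnorm(3), c("a", "b", "c")),
                     scale = stats::setNames(runif(3), c("a", "b", "c")),
                     dropped = "gZ")
  path <- tempfile(fileext = ".json")
  writeSVRModel(fit, path)
  back <- readSVRModel(path)
  expect_identical(back@dualCoefs, fit@dualCoefs)
  expect_identical(unname(back@supportVectors), unname(fit@supportVectors))
  expect_identical(back@intercept, fit@intercept)
  expect_identical(back@geneIds, fit@geneIds)
  expect_identical(back@kernel@gamma, fit@kernel@gamma)
  expect_identical(as.numeric(back@scaler$center), as.numeric(fit@scaler$center))
  x <- matrix(rnorm(80), 2, 40, dimnames = list(NULL, colnames(tt$x)))
  expect_identical(predictSVR(back, x), predictSVR(fit, x))
})
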