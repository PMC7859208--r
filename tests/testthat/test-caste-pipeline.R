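# A compact but complete scenario for fast end-to-end checks.
smallScenario <- function(seed = 1) {
  simulateDataset(simulationConfig(
    n_genes = 150, n_informative = 25, n_age_genes = 25, n_queens = 12,
    n_workers = 10, n_qr = 20, caste_effect = 2, seed = seed))
}

smallModel <- function(ds, seed = 1) {
  trainCasteClassifier(ds$se, repeats = 2, stopSize = 40, seed = seed)
}

test_that("training separates castes and classification reuses training statistics", {
  ds <- smallScenario(seed = 21)
  sel <- smallModel(ds, seed = 21)
  rep <- classifySamples(sel, ds$se)
  est <- rep$estimates
  qmin <- min(est$estimate[est$group == "queen"])
  wmax <- max(est$estimate[est$group == "control_worker"])
  expect_gt(qmin - wmax, 0.5)
  ## group summaries recompute exactly from per-sample estimates
  byHand <- tapply(est$estimate, est$group, mean)
  expect_equal(rep$groups$mean, as.numeric(byHand[rep$groups$group]),
               tolerance = 1e-12)
  ## queens' training estimates hug 1 within the tube
  expect_lt(abs(rep$groups$mean[rep$groups$group == "queen"] - 1),
            sel@model@epsilon + 0.05)
  ## duplicating a training worker's profile reproduces its estimate exactly
  cts <- SummarizedExperiment::assay(ds$se, "counts")
  samples <- as.data.frame(SummarizedExperiment::colData(ds$se))
  w1 <- which(samples$group == "control_worker")[1]
  dup <- cts[, c(w1, w1)]
  colnames(dup) <- c("copyA", "copyB")
  rep2 <- classifySamples(sel, dup,
                          tinySamples(c("copyA", "copyB"),
                                      rep("control_worker", 2)))
  expect_equal(rep2$estimates$estimate[1],
               est$estimate[est$sample_id == samples$sample_id[w1]],
               tolerance = 1e-10)
  expect_identical(rep2$estimates$estimate[1], rep2$estimates$estimate[2])
  ## missing model genes are reported
  expect_error(classifySamples(sel, cts[-match(sel@genes[1], rownames(cts)), ],
                               samples), "absent")
})

test_that("QR estimates track the latent state and the timepoint test behaves", {
  ds <- smallScenario(seed = 22)
  sel <- smallModel(ds, seed = 22)
  rep <- classifySamples(sel, ds$se)
  est <- rep$estimates
  qr <- est$group %in% c("qr_day3", "qr_day12")
  t <- ds$truth$latent$t[match(est$sample_id[qr], ds$truth$latent$sample_id)]
  expect_gte(cor(est$estimate[qr], t, method = "spearman"), 0.8)

  cmp <- compareQRTimepoints(rep)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  expect_equal(cmp$qr_day3$n + cmp$qr_day12$n, sum(qr))

  ## degenerate: identical estimate vectors in both groups
  fake <- rep
  fake$estimates <- data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("qr_day3", "qr_day12"), each = 4),
    estimate = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  expect_gte(compareQRTimepoints(fake)$p, 0.99)
  ## fully ordered groups give W = 0
  fake$estimates$estimate <- c(0.1, 0.2, 0.15, 0.12, 0.3, 0.4, 0.35, 0.5)
  expect_equal(compareQRTimepoints(fake)$W, 0)
})

test_that("label swap maps estimates to their complements", {
  tt <- tinyTrainingSet(seed = 23, nGenes = 20, nInf = 5)
  spec <- kernelSpec("radial", gamma = 1 / 20)
  f1 <- fitSVR(tt$x, tt$y, spec, cost = 8)
  f2 <- fitSVR(tt$x, 1 - tt$y, spec, cost = 8)
  q <- tt$x[1:5, ]
  expect_equal(predictSVR(f2, q), 1 - predictSVR(f1, q), tolerance = 1e-6)
})

test_that("degenerate training sizes run with a capped-fold warning", {
  ds <- smallScenario(seed = 24)
  cts <- SummarizedExperiment::assay(ds$se, "counts")
  samples <- as.data.frame(SummarizedExperiment::colData(ds$se))
  keep <- c(which(samples$group == "queen")[1],
            which(samples$group == "control_worker")[1])
  expect_warning(
    sel <- trainCasteClassifier(cts[, keep], samples[keep, ], repeats = 1,
                                stopSize = 10, seed = 1),
    "fold")
  expect_s4_class(sel, "SelectedModel")
})

test_that("phenotype models recover constructed relationships and flag degeneracies", {
  n <- 30
  set.seed(25)
  age <- sample(5:30, n, replace = TRUE)
  samples <- data.frame(sample_id = paste0("s", 1:n),
                        group = rep(c("qr_day3", "qr_day12"), length.out = n),
                        age = age,
                        ovarian_index = 2 + 3 * age,  # perfectly age-determined
                        dominance = rnorm(n, 1500, 50),
                        queenness = runif(n))
  rep <- list(estimates = data.frame(sample_id = samples$sample_id,
                                     group = samples$group,
                                     estimate = 2 * age))
  class(rep) <- "ClassificationReport"
  pm <- fitPhenotypeModels(rep, samples)
  ageRow <- pm[pm$predictor == "age", ]
  expect_equal(ageRow$slope, 2, tolerance = 1e-10)
  expect_lt(ageRow$se, 1e-10)
  expect_equal(ageRow$r, 1, tolerance = 1e-12)
  ## phenotype perfectly linear in age -> residuals zero-variance -> flagged
  ovrRow <- pm[pm$predictor == "ovarian_resid_age", ]
  expect_match(ovrRow$note, "zero-variance")
  expect_true(is.na(ovrRow$slope))
})

test_that("queenness is a calibrated logistic score of ovary and dominance", {
  ## 12-point toy: coefficients match the independent IRLS oracle at lambda 0
  set.seed(26)
  n <- 12
  ov <- c(rnorm(6, 2, 1), rnorm(6, 6, 1))
  dom <- c(rnorm(6, 1400, 80), rnorm(6, 1600, 80))
  grp <- rep(c("control_worker", "queen"), each = 6)
  ## inject overlap so the data are not separable
  ov[6] <- 6.5; ov[7] <- 1.8
  samples <- data.frame(sample_id = paste0("s", 1:n), group = grp, age = 1:n,
                        ovarian_index = ov, dominance = dom,
                        queenness = NA_real_)
  out <- phenotypeQueenness(samples)
  Z <- cbind(1, scale(ov), scale(dom))
  ## rescale to the training standardization used internally
  Zint <- cbind(1, (ov - mean(ov)) / sd(ov), (dom - mean(dom)) / sd(dom))
  beta <- oracleIRLS(Zint, as.numeric(grp == "queen"))
  expect_equal(out$queenness, as.numeric(stats::plogis(Zint %*% beta)),
               tolerance = 1e-4)
  ## a sample exactly on the fitted boundary scores 0.5
  x2 <- 1.3
  x3 <- -(beta[1] + beta[2] * x2) / beta[3]
  bnd <- samples[1, ]
  bnd$sample_id <- "boundary"; bnd$group <- "qr_day3"
  bnd$ovarian_index <- mean(ov) + x2 * sd(ov)
  bnd$dominance <- mean(dom) + x3 * sd(dom)
  out2 <- phenotypeQueenness(rbind(samples, bnd))
  expect_equal(out2$queenness[out2$sample_id == "boundary"], 0.5,
               tolerance = 1e-4)

  ## noiseless monotone phenotypes: separable -> warned ridge fallback,
  ## and every queen outranks every worker
  truth <- data.frame(sample_id = paste0("t", 1:16),
                      t = rep(c(1, 0), each = 8))
  ph <- simulatePhenotypes(truth, noise_sd = 0, seed = 1)
  sep <- data.frame(sample_id = truth$sample_id,
                    group = rep(c("queen", "control_worker"), each = 8),
                    age = 1:16, ovarian_index = ph$ovarian_index,
                    dominance = ph$dominance, queenness = NA_real_)
  expect_warning(outSep <- phenotypeQueenness(sep), "separation")
  expect_gt(min(outSep$queenness[1:8]), max(outSep$queenness[9:16]))
})

test_that("gene-set comparisons delegate to the overlap statistics", {
  u <- paste0("g", 1:10)
  same <- compareGeneSets(u[1:4], u[1:4], u)
  expect_equal(same@jaccard, 1)
  disj <- compareGeneSets(u[1:5], u[6:9], u)
  expect_equal(disj@jaccard, 0)
  expect_gte(disj@p, 0.5)
  ex <- compareGeneSets(u[1:5], u[1:4], u)
  expect_equal(ex@p, 1 / 42, tolerance = 1e-12)
  expect_error(compareGeneSets(c("zz"), u[1:3], u), "universe")
})
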