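test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simulationConfig(dispersion = 0), "dispersion")
  expect_error(simulationConfig(caste_effect = -1), "caste_effect")
  expect_error(simulationConfig(depth_mean = -5), "depth_mean")
  expect_error(simulationConfig(n_genes = 10.5), "n_genes")
  expect_error(simulationConfig(n_genes = 100, n_informative = 60,
                                n_age_genes = 60), "n_informative")
  expect_silent(simulationConfig(n_genes = 100, n_informative = 60,
                                 n_age_genes = 60, allow_overlap = TRUE))
})

test_that("dimensions, group sizes and truth bookkeeping are conserved", {
  cfg <- simulationConfig(n_genes = 300, n_informative = 20, n_age_genes = 20,
                          n_queens = 5, n_workers = 4, n_qr = 7, seed = 2)
  ds <- simulateDataset(cfg)
  cts <- SummarizedExperiment::assay(ds$se, "counts")
  expect_identical(dim(cts), c(300L, 16L))
  grp <- SummarizedExperiment::colData(ds$se)$group
  expect_identical(sum(grp == "queen"), 5L)
  expect_identical(sum(grp == "control_worker"), 4L)
  expect_identical(sum(grp %in% c("qr_day3", "qr_day12")), 7L)
  expect_true(all(ds$truth$informative$gene %in% rownames(cts)))
  expect_true(all(ds$truth$age_genes$gene %in% rownames(cts)))
  expect_length(intersect(ds$truth$informative$gene,
                          ds$truth$age_genes$gene), 0)
  ## latent-state invariants
  lt <- ds$truth$latent
  expect_true(all(lt$t[lt$group == "queen"] == 1))
  expect_true(all(lt$t[lt$group == "control_worker"] == 0))
  qr <- lt$t[grepl("^qr", lt$group)]
  expect_true(all(qr > 0 & qr < 1))
  expect_true(all(cts >= 0) && all(cts == round(cts)))
})

test_that("regeneration with the same config is byte-identical", {
  cfg <- simulationConfig(n_genes = 150, n_informative = 10, n_age_genes = 10,
                          n_queens = 4, n_workers = 4, n_qr = 6, seed = 9)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(d1$se, "counts"),
                   SummarizedExperiment::assay(d2$se, "counts"))
  expect_identical(d1$truth, d2$truth)
  dir1 <- tempfile(); dir2 <- tempfile()
  writeDataset(d1, dir1); writeDataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("with no planted effects empirical fold changes centre on zero", {
  cfg <- simulationConfig(caste_effect = 0, age_effect = 0, seed = 3)
  ds <- simulateDataset(cfg)
  cts <- SummarizedExperiment::assay(ds$se, "counts")
  grp <- SummarizedExperiment::colData(ds$se)$group
  e <- normalizeLogCPM(cts)
  lfc <- rowMeans(e[, grp == "queen"]) - rowMeans(e[, grp == "control_worker"])
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("planted genes show the configured fold change", {
  cfg <- simulationConfig(n_informative = 50, caste_effect = 1.0, seed = 1)
  ds <- simulateDataset(cfg)
  cts <- SummarizedExperiment::assay(ds$se, "counts")
  grp <- SummarizedExperiment::colData(ds$se)$group
  e <- normalizeLogCPM(cts)
  lfc <- rowMeans(e[, grp == "queen"]) - rowMeans(e[, grp == "control_worker"])
  med <- stats::median(abs(lfc[ds$truth$informative$gene]))
  expect_lt(abs(med - 1.0), 0.25)
})

test_that("QR latent states track age at the configured correlation", {
  cfg <- simulationConfig(n_genes = 10, n_informative = 0, n_age_genes = 0,
                          n_qr = 300, t_age_correlation = 0.4832, seed = 4)
  ds <- simulateDataset(cfg)
  lt <- ds$truth$latent
  qr <- grepl("^qr", lt$group)
  expect_lt(abs(cor(lt$t[qr], lt$age[qr]) - 0.4832), 0.12)
})

test_that("noiseless phenotypes are strictly monotone in the latent state", {
  truth <- data.frame(sample_id = paste0("s", 1:20),
                      t = c(rep(1, 5), rep(0, 5), seq(0.05, 0.95, length.out = 10)))
  ph <- simulatePhenotypes(truth, noise_sd = 0, seed = 1)
  expect_equal(cor(truth$t, ph$ovarian_index, method = "spearman"), 1)
  expect_true(min(ph$ovarian_index[1:5]) > max(ph$ovarian_index[6:10]))
  expect_true(min(ph$dominance[1:5]) > max(ph$dominance[6:10]))
  expect_error(simulatePhenotypes(truth, noise_sd = -1), "nonnegative")
})

test_that("default phenotype noise yields the intended latent correlation", {
  rs <- vapply(1:20, function(s) {
    t <- c(rep(1, 16), rep(0, 8), stats::rbeta(36, 2, 4))
    truth <- data.frame(sample_id = paste0("s", seq_along(t)), t = t)
    ph <- simulatePhenotypes(truth, noise_sd = 3.8, seed = s)
    cor(t, ph$ovarian_index)
  }, 0)
  expect_true(all(rs > 0.5 & rs < 0.85))
})

test_that("planted effects are recoverable per gene and the null is calibrated", {
  ## recovery: Welch test on log2-CPM (the DE stand-in at threshold 0)
  cfg <- simulationConfig(n_genes = 400, n_informative = 40, n_age_genes = 0,
                          n_queens = 26, n_workers = 12, n_qr = 0,
                          caste_effect = 1.0, seed = 11)
  ds <- simulateDataset(cfg)
  de <- deTest(ds$se, lfcThreshold = 0)
  hit <- mean(ds$truth$informative$gene %in% de$gene[de$significant])
  expect_gte(hit, 0.70)

  ## null calibration: no planted effect, BH-flagged fraction small
  cfg0 <- simulationConfig(n_genes = 400, n_informative = 0, n_age_genes = 0,
                           caste_effect = 0, age_effect = 0, n_qr = 0,
                           n_queens = 13, n_workers = 12, seed = 12)
  ds0 <- simulateDataset(cfg0)
  de0 <- deTest(ds0$se, lfcThreshold = 0)
  expect_lte(mean(de0$significant), 0.10)
})
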