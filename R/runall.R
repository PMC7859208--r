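#' Pipeline configuration
#'
#' Builds a validated configuration for [runAll()]. The classifier defaults
#' are the operating point found by the broad kernel comparison on
#' transcriptome-scale data — radial kernel, gamma = 1e-6, C = 2^5, with
#' threefold cross-validation repeated 20 times and elimination down to 100
#' genes. gamma may be the string `"auto"` (1/p on the standardized matrix),
#' which is appropriate at the much smaller gene counts of the synthetic
#' demo data (see `inst/config/synthetic-demo.yaml`).
#'
#' @param counts,samples input TSV paths, or NULL to simulate.
#' @param outdir artifact directory.
#' @param seed master seed; per-stage seeds are fanned out deterministically
#'   by hashing the stage name.
#' @param simulation list of overrides for [simulationConfig()].
#' @param filter_threshold expression-filter count threshold.
#' @param pseudocount log2-CPM pseudocount.
#' @param kernel kernel kind.
#' @param gamma kernel gamma, or `"auto"`.
#' @param degree,coef0 polynomial/sigmoid kernel parameters.
#' @param cost,epsilon SVR hyperparameters.
#' @param k,repeats,stop_size cross-validation and elimination settings.
#' @param grid_search run the refined radial grid search before elimination.
#' @param lfc_threshold DE stand-in interval-null half-width (log2 scale).
#' @param alpha DE significance level.
#' @param lambda queenness logistic ridge penalty.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(counts = NULL, samples = NULL, outdir = "results",
                           seed = 1, simulation = list(),
                           filter_threshold = 20, pseudocount = 1,
                           kernel = "radial", gamma = 1e-6, degree = 3,
                           coef0 = 0, cost = 2^5, epsilon = 0.1, k = 3,
                           repeats = 20, stop_size = 100,
                           grid_search = FALSE, lfc_threshold = log2(1.5),
                           alpha = 0.05, lambda = 0) {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config field 'seed' must be an integer")
  for (f in c("k", "repeats", "stop_size"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("config field '", f, "' must be a positive integer")
  if (!identical(cfg$gamma, "auto") &&
      (!is.numeric(cfg$gamma) || cfg$gamma <= 0))
    stop("config field 'gamma' must be positive or \"auto\"")
  if (!cfg$kernel %in% c("radial", "linear", "sigmoid", "polynomial"))
    stop("config field 'kernel' must name one of the four kernels")
  if (cfg$cost <= 0) stop("config field 'cost' must be positive")
  if (cfg$epsilon < 0) stop("config field 'epsilon' must be nonnegative")
  if (!is.list(cfg$simulation)) stop("config field 'simulation' must be a list")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; known keys override [pipelineConfig()]
#' defaults.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

stageSeed_ <- function(seed, stage) {
  seedStream(seed, sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))))
}

#' Run the full caste-classification pipeline
#'
#' Executes simulate (when no input paths are given), filter, queenness
#' fitting, train (grid search optional, then recursive feature
#' elimination), classify, the downstream statistics, the DE stand-in and
#' the summary report, writing every artifact plus a manifest (input hashes,
#' config, seed, versions) under `config$outdir`. Identical configurations
#' produce byte-identical tables and manifests.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param verbose log elimination iterations to stderr.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runAll <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  inputs <- character(0)
  res <- list()
  if (is.null(config$counts)) {
    res$dataset <- stage("simulate", {
      simArgs <- utils::modifyList(list(seed = stageSeed_(config$seed, "simulate")),
                                   config$simulation)
      ds <- simulateDataset(do.call(simulationConfig, simArgs))
      writeDataset(ds, file.path(out, "data"))
      ds
    })
    counts <- SummarizedExperiment::assay(res$dataset$se, "counts")
    samples <- as.data.frame(SummarizedExperiment::colData(res$dataset$se))
  } else {
    counts <- stage("read", readCounts(config$counts))
    samples <- stage("read", readSampleTable(config$samples))
    inputs <- c(config$counts, config$samples)
  }

  res$filtered <- stage("filter", {
    f <- filterLowCounts(counts, samples, threshold = config$filter_threshold)
    writeCounts(f, file.path(out, "filtered_counts.tsv"))
    f
  })

  res$samples <- stage("queenness", {
    s <- phenotypeQueenness(samples, lambda = config$lambda)
    writeSampleTable(s, file.path(out, "samples_with_queenness.tsv"))
    s
  })

  res$selected <- stage("train", {
    spec <- if (identical(config$gamma, "auto")) NULL
      else if (config$kernel == "linear") kernelSpec("linear")
      else kernelSpec(config$kernel, gamma = config$gamma,
                      degree = config$degree, coef0 = config$coef0)
    grid <- if (isTRUE(config$grid_search)) refinedGrid() else NULL
    sel <- trainCasteClassifier(
      res$filtered, res$samples, spec = spec, cost = config$cost,
      epsilon = config$epsilon, k = config$k, repeats = config$repeats,
      stopSize = config$stop_size, grid = grid,
      filterThreshold = config$filter_threshold,
      pseudocount = config$pseudocount,
      seed = stageSeed_(config$seed, "train"), verbose = verbose)
    writeRFETrace(attr(sel, "trace"), file.path(out, "rfe_trace.tsv"))
    writeGeneSet(sel@genes, file.path(out, "selected_genes.txt"))
    mdl <- sel@model
    mdl@scaler <- list(center = sel@scaler$center[sel@genes],
                       scale = sel@scaler$scale[sel@genes])
    writeSVRModel(mdl, file.path(out, "svr_model.json"))
    sel
  })

  res$report <- stage("classify", {
    rep <- classifySamples(res$selected, res$filtered, res$samples)
    writeTSV(rep$estimates, file.path(out, "classifications.tsv"))
    rep
  })

  res$qr <- stage("stats", {
    if (all(c("qr_day3", "qr_day12") %in% res$report$estimates$group))
      compareQRTimepoints(res$report) else NULL
  })
  res$phenotype_models <- stage("stats", {
    pm <- fitPhenotypeModels(res$report, res$samples)
    writeTSV(pm, file.path(out, "phenotype_models.tsv"))
    pm
  })

  res$de <- stage("de", {
    de <- deTest(res$filtered, res$samples, lfcThreshold = config$lfc_threshold,
                 alpha = config$alpha)
    writeDETable(de, file.path(out, "de_results.tsv"))
    de0 <- deTest(res$filtered, res$samples, lfcThreshold = 0,
                  alpha = config$alpha)
    writeDETable(de0, file.path(out, "de_results_nothreshold.tsv"))
    list(thresholded = de, unthresholded = de0)
  })

  res$overlaps <- stage("stats", {
    rows <- list()
    addOv <- function(name, other) {
      ov <- compareGeneSets(res$selected, intersect(other, res$selected@universe))
      rows[[name]] <<- data.frame(
        comparison = name, overlap = ov@overlap, size_svm = ov@sizeA,
        size_other = ov@sizeB, universe = ov@universe,
        jaccard = ov@jaccard, hypergeom_p = ov@p, stringsAsFactors = FALSE)
    }
    addOv("svm_vs_de_threshold",
          res$de$thresholded$gene[res$de$thresholded$significant])
    addOv("svm_vs_de_nothreshold",
          res$de$unthresholded$gene[res$de$unthresholded$significant])
    if (!is.null(res$dataset)) {
      addOv("svm_vs_planted_informative", res$dataset$truth$informative$gene)
      addOv("svm_vs_planted_age", res$dataset$truth$age_genes$gene)
    }
    ov <- do.call(rbind, rows)
    rownames(ov) <- NULL
    writeTSV(ov, file.path(out, "overlaps.tsv"))
    ov
  })

  stage("report", {
    trace <- traceTable(attr(res$selected, "trace"))
    summary <- list(
      classification = res$report$groups,
      cv = list(full_model_mse = trace$cv_error[1],
                full_model_rmse = sqrt(trace$cv_error[1]),
                selected_mse = res$selected@cvError,
                selected_rmse = sqrt(res$selected@cvError),
                n_selected_genes = length(res$selected@genes)),
      qr_comparison = res$qr,
      phenotype_models = res$phenotype_models,
      overlaps = res$overlaps,
      de = list(label = "DE stand-in",
                n_significant_threshold = sum(res$de$thresholded$significant),
                n_significant_nothreshold = sum(res$de$unthresholded$significant)))
    writeLines(jsonlite::toJSON(summary, digits = 15, auto_unbox = TRUE,
                                pretty = TRUE, dataframe = "rows",
                                null = "null"),
               file.path(out, "summary.json"))
  })

  stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.json"))
    hashes <- unname(tools::md5sum(file.path(out, files)))
    manifest <- list(
      seed = config$seed,
      config = unclass(config)[setdiff(names(config), "outdir")],
      inputs = if (length(inputs))
        as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
        else stats::setNames(list(), character(0)),
      artifacts = as.list(stats::setNames(as.list(hashes), files)),
      versions = list(casteSVM = as.character(packageVersion("casteSVM")),
                      R = paste(R.version$major, R.version$minor, sep = ".")))
    writeLines(jsonlite::toJSON(manifest, digits = 15, auto_unbox = TRUE,
                                pretty = TRUE, null = "null"),
               file.path(out, "manifest.json"))
  })

  invisible(res)
}
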