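# Shared fixtures. The reference scenario (500 genes, 50 planted
# caste-informative at |log2FC| = 1.5, 50 disjoint age genes, 26 queens + 12
# control workers + 58 QR individuals, elimination with 5 CV repeats down to
# 100 genes) is expensive, so runs are memoized per seed and shared across
# test files.

.refCache <- new.env(parent = emptyenv())

referenceRun <- function(seed) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .refCache)) {
    cfg <- simulationConfig(n_genes = 500, n_informative = 50,
                            n_age_genes = 50, n_queens = 26, n_workers = 12,
                            n_qr = 58, caste_effect = 1.5, seed = seed)
    ds <- simulateDataset(cfg)
    sel <- trainCasteClassifier(ds$se, repeats = 5, stopSize = 100,
                                seed = seed)
    report <- classifySamples(sel, ds$se)
    assign(key, list(ds = ds, sel = sel, report = report), envir = .refCache)
  }
  get(key, envir = .refCache)
}

# Small labeled training problem for fast unit tests: strong caste signal in
# the first `nInf` genes.
tinyTrainingSet <- function(seed = 1, nGenes = 40, nInf = 8, n1 = 10, n0 = 8) {
  set.seed(seed)
  y <- c(rep(1, n1), rep(0, n0))
  x <- matrix(rnorm((n1 + n0) * nGenes), n1 + n0, nGenes)
  x[, seq_len(nInf)] <- x[, seq_len(nInf)] + 2 * y
  colnames(x) <- sprintf("g%03d", seq_len(nGenes))
  rownames(x) <- sprintf("s%02d", seq_len(n1 + n0))
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(x = x, y = y)
}

# Minimal sample table matching a small count matrix built in a test.
tinySamples <- function(ids, groups) {
  data.frame(sample_id = ids, group = groups,
             age = seq_along(ids) + 4,
             ovarian_index = NA_real_, dominance = NA_real_,
             queenness = NA_real_, stringsAsFactors = FALSE)
}
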