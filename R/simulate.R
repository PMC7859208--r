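#' Configuration for the queen-removal study simulator
#'
#' Defaults emulate the sequenced study design: 26 queens and 12 control
#' workers for training plus 58 queen-removal (QR) individuals (24 sampled at
#' day 3, 34 at day 12), a planted set of caste-informative genes at
#' |log2 fold change| = 1.5 (the conventional biological-relevance
#' threshold), a disjoint set of age-responsive genes, negative-binomial
#' counts with dispersion 0.2 (variance = mu + phi * mu^2) and a latent QR
#' caste state correlated with age at 0.4832, the reported queenness-age
#' correlation.
#'
#' @param n_genes number of genes.
#' @param n_informative number of planted caste-informative genes.
#' @param n_age_genes number of planted age-responsive genes (disjoint from
#'   the informative set unless `allow_overlap`).
#' @param n_queens,n_workers,n_qr group sizes.
#' @param qr_day3_fraction fraction of QR individuals sampled at day 3.
#' @param caste_effect |log2 fold change| of informative genes between the
#'   pure castes (t = 1 vs t = 0).
#' @param age_effect |log2 fold change| of age genes per standardized
#'   maturation unit.
#' @param dispersion negative-binomial dispersion phi.
#' @param depth_mean expected library size (reads).
#' @param depth_cv coefficient of variation of library size.
#' @param t_age_correlation target Pearson correlation between the latent QR
#'   caste state and age.
#' @param phenotype_noise_sd Gaussian noise (on the 0-10 ovarian-index scale)
#'   added by [simulatePhenotypes()]; the default is calibrated so the
#'   phenotype-latent state correlation is about 0.7.
#' @param allow_overlap allow informative and age gene sets to overlap.
#' @param seed master random seed.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 2000, n_informative = 100,
                             n_age_genes = 100, n_queens = 26,
                             n_workers = 12, n_qr = 58,
                             qr_day3_fraction = 24 / 58,
                             caste_effect = 1.5, age_effect = 0.5,
                             dispersion = 0.2, depth_mean = 1e6,
                             depth_cv = 0.2, t_age_correlation = 0.4832,
                             phenotype_noise_sd = 3.8,
                             allow_overlap = FALSE, seed = 1) {
  cfg <- list(n_genes = n_genes, n_informative = n_informative,
              n_age_genes = n_age_genes, n_queens = n_queens,
              n_workers = n_workers, n_qr = n_qr,
              qr_day3_fraction = qr_day3_fraction,
              caste_effect = caste_effect, age_effect = age_effect,
              dispersion = dispersion, depth_mean = depth_mean,
              depth_cv = depth_cv, t_age_correlation = t_age_correlation,
              phenotype_noise_sd = phenotype_noise_sd,
              allow_overlap = isTRUE(allow_overlap), seed = seed)
  counts <- c("n_genes", "n_informative", "n_age_genes", "n_queens",
              "n_workers", "n_qr")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("invalid configuration field '", f, "': must be a nonnegative integer")
  if (!cfg$allow_overlap && cfg$n_informative + cfg$n_age_genes > cfg$n_genes)
    stop("invalid configuration field 'n_informative': ",
         "n_informative + n_age_genes exceeds n_genes with disjoint sets")
  if (cfg$caste_effect < 0)
    stop("invalid configuration field 'caste_effect': must be >= 0")
  if (cfg$age_effect < 0)
    stop("invalid configuration field 'age_effect': must be >= 0")
  if (cfg$dispersion <= 0)
    stop("invalid configuration field 'dispersion': must be > 0")
  if (cfg$depth_mean <= 0)
    stop("invalid configuration field 'depth_mean': must be > 0")
  if (cfg$depth_cv < 0)
    stop("invalid configuration field 'depth_cv': must be >= 0")
  if (abs(cfg$t_age_correlation) >= 1)
    stop("invalid configuration field 't_age_correlation': |r| must be < 1")
  if (cfg$qr_day3_fraction < 0 || cfg$qr_day3_fraction > 1)
    stop("invalid configuration field 'qr_day3_fraction': must lie in [0, 1]")
  if (cfg$phenotype_noise_sd < 0)
    stop("invalid configuration field 'phenotype_noise_sd': must be >= 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

## QR latent states sit in (0, 1) as Beta(2, 4) draws coupled to age through
## a Gaussian copula. The copula correlation needed to hit a target Pearson
## correlation after both monotone transforms is solved numerically once, on
## a fixed internal seed, by interpolating the empirical response curve.
copulaRhoFor <- function(target, shape1 = 2, shape2 = 4) {
  if (target == 0) return(0)
  s <- sign(target); a <- abs(target)
  rhos <- seq(0, 0.995, by = 0.05)
  attained <- withSeed(104729, {
    z1 <- rnorm(20000); z2 <- rnorm(20000)
    age <- stats::qunif(pnorm(z1), 3, 30)
    vapply(rhos, function(r) {
      t <- qbeta(pnorm(r * z1 + sqrt(1 - r^2) * z2), shape1, shape2)
      cor(t, age)
    }, 0)
  })
  if (a >= max(attained)) return(s * 0.995)
  s * stats::approx(attained, rhos, xout = a, ties = "ordered")$y
}

#' Simulate a queen-removal transcriptome dataset
#'
#' Counts for gene g in sample i are negative binomial with mean
#' \eqn{s_i q_g 2^{\beta_g t_i + \delta_g m_i}}: \eqn{q_g} is a lognormal
#' baseline abundance, \eqn{s_i} the library-size factor,
#' \eqn{t_i \in [0,1]} the latent transcriptomic caste state (queens exactly
#' 1, control workers exactly 0, QR individuals intermediate Beta draws
#' correlated with age), and \eqn{m_i} a standardized within-season
#' maturation covariate driving the age-responsive genes. Maturation equals
#' standardized adult age for workers and QR individuals; overwintered queens
#' (chronological age ~200 days) receive maturation states drawn from the
#' same within-season distribution rather than an extrapolation of the young
#' trajectory, which keeps the planted age axis orthogonal to caste.
#'
#' @param config a [simulationConfig()].
#' @return list of class `SimulatedDataset` with elements `se` (a
#'   [CasteExperiment-class]), `truth` (list: `latent` data.frame with t,
#'   age, maturation and size factor per sample; `informative` and
#'   `age_genes` data.frames with per-gene effect signs) and `config`.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, config)
  G <- config$n_genes
  nq <- config$n_queens; nw <- config$n_workers; nr <- config$n_qr
  n <- nq + nw + nr
  genes <- sprintf("g%05d", seq_len(G))
  ageMean <- 16.5; ageSD <- 27 / sqrt(12)  # U(3, 30) moments

  out <- withSeed(config$seed, {
    informative <- sort(sample(genes, config$n_informative))
    pool <- if (config$allow_overlap) genes else setdiff(genes, informative)
    ageGenes <- sort(sample(pool, config$n_age_genes))
    beta <- stats::setNames(numeric(G), genes)
    beta[informative] <- sample(c(-1, 1), config$n_informative, TRUE) *
      config$caste_effect
    delta <- stats::setNames(numeric(G), genes)
    delta[ageGenes] <- sample(c(-1, 1), config$n_age_genes, TRUE) *
      config$age_effect

    q <- exp(rnorm(G, 0, 1.2)); q <- q / sum(q)

    ageQ <- round(200 + rnorm(nq, 0, 15))
    matQ <- (runif(nq, 3, 30) - ageMean) / ageSD
    ageW <- round(runif(nw, 3, 30))
    rho <- copulaRhoFor(config$t_age_correlation)
    z1 <- rnorm(nr); z2 <- rnorm(nr)
    ageR <- round(stats::qunif(pnorm(z1), 3, 30))
    tR <- qbeta(pnorm(rho * z1 + sqrt(1 - rho^2) * z2), 2, 4)
    tR <- pmin(pmax(tR, 1e-6), 1 - 1e-6)

    t <- c(rep(1, nq), rep(0, nw), tR)
    age <- c(ageQ, ageW, ageR)
    maturation <- c(matQ, (c(ageW, ageR) - ageMean) / ageSD)
    sdlog <- sqrt(log(1 + config$depth_cv^2))
    sizeFactor <- rlnorm(n, -sdlog^2 / 2, sdlog)
    depth <- config$depth_mean * sizeFactor

    n3 <- round(config$qr_day3_fraction * nr)
    ids <- c(sprintf("Q%02d", seq_len(nq)), sprintf("W%02d", seq_len(nw)),
             sprintf("QR%02d", seq_len(nr)))
    group <- c(rep("queen", nq), rep("control_worker", nw),
               rep("qr_day3", n3), rep("qr_day12", nr - n3))

    mu <- (q %o% depth) * 2^(beta %o% t + delta %o% maturation)
    counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / config$dispersion),
                     G, n, dimnames = list(genes, ids))

    latent <- data.frame(sample_id = ids, group = group, t = t, age = age,
                         maturation = maturation, size_factor = sizeFactor,
                         stringsAsFactors = FALSE)
    list(counts = counts, latent = latent,
         informative = data.frame(gene = informative,
                                  sign = sign(beta[informative]),
                                  stringsAsFactors = FALSE),
         age_genes = data.frame(gene = ageGenes,
                                sign = sign(delta[ageGenes]),
                                stringsAsFactors = FALSE))
  })

  phen <- simulatePhenotypes(out$latent, noise_sd = config$phenotype_noise_sd,
                             seed = seedStream(config$seed, 9973))
  samples <- data.frame(sample_id = out$latent$sample_id,
                        group = out$latent$group, age = out$latent$age,
                        ovarian_index = phen$ovarian_index,
                        dominance = phen$dominance,
                        queenness = NA_real_, stringsAsFactors = FALSE)
  ds <- list(se = CasteExperiment(out$counts, samples),
             truth = list(latent = out$latent,
                          informative = out$informative,
                          age_genes = out$age_genes),
             config = config)
  class(ds) <- "SimulatedDataset"
  ds
}

#' Simulate phenotype measurements from latent caste states
#'
#' Ovarian index (0-10 scale) and dominance (Elo-type rating around 1500)
#' are strictly monotone functions of the latent state t plus Gaussian
#' noise; `noise_sd` is on the ovarian scale and is rescaled by the ratio of
#' the two phenotype ranges for dominance. Queenness is left unfitted (NA);
#' [phenotypeQueenness()] fills it.
#'
#' @param truth data.frame with columns `sample_id` and `t`.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed random seed.
#' @return data.frame (sample_id, ovarian_index, dominance, queenness = NA).
#' @export
simulatePhenotypes <- function(truth, noise_sd = 3.8, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(truth$t) || any(!is.finite(truth$t)))
    stop("truth must provide a finite latent state t for every sample")
  n <- nrow(truth)
  withSeed(seed, {
    ovarian <- 10 * truth$t + rnorm(n, 0, noise_sd)
    dominance <- 1500 + 400 * (truth$t - 0.5) + rnorm(n, 0, 40 * noise_sd)
    data.frame(sample_id = truth$sample_id, ovarian_index = ovarian,
               dominance = dominance, queenness = NA_real_,
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv` (genes x samples), `samples.tsv`, `truth.tsv` (latent
#' states) and the planted gene sets as one-identifier-per-line text files.
#'
#' @param ds a `SimulatedDataset` from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(inherits(ds, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(SummarizedExperiment::assay(ds$se, "counts"),
              file.path(dir, "counts.tsv"))
  writeSampleTable(as.data.frame(SummarizedExperiment::colData(ds$se)),
                   file.path(dir, "samples.tsv"))
  writeTSV(ds$truth$latent, file.path(dir, "truth.tsv"))
  writeGeneSet(ds$truth$informative$gene,
               file.path(dir, "informative_genes.txt"))
  writeGeneSet(ds$truth$age_genes$gene, file.path(dir, "age_genes.txt"))
  invisible(dir)
}
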