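# casteSVM

Continuous transcriptomic caste classification for primitively eusocial
insects, from a bulk RNA-seq count matrix.

In *Polistes* paper wasps, queen loss triggers a succession process in which
some workers shift towards the queen phenotype. Gene-by-gene differential
expression can rank caste-biased genes, but it cannot place an *individual*
between castes. `casteSVM` does: it trains an ε-insensitive support-vector
regression (worker = 0, queen = 1) on queen and control-worker brain
transcriptomes, prunes the gene set by recursive feature elimination under
repeated threefold cross-validation, and then scores queen-removal
individuals on a continuous queen–worker axis,

> f(x) = Σᵢ αᵢ K(sᵢ, x) + b,  K(x, y) = exp(−γ |x − y|²),

with estimates deliberately unclipped (queen-side values slightly above 1
are meaningful). Each elimination step records the repeated-CV mean squared
error of the current gene set, fits on all training samples, ranks genes by
the weight vector **w** = αᵀS (dual coefficients × support vectors), and
drops the gene with the smallest |w|; the selected classifier is the
iteration with minimal CV error. Downstream statistics link the estimates to
phenotype (queenness, ovarian development, dominance, age; OLS and
age-residualized OLS), compare queen-removal timepoints (Wilcoxon rank-sum),
and measure gene-set overlaps (Jaccard + one-sided hypergeometric). A seeded
negative-binomial simulator reproduces the statistical structure of the
queen-removal study design, so the entire pipeline is testable without the
original sequencing data.

## Worked example

```r
library(casteSVM)

## synthetic queen-removal study: 26 queens + 12 workers (training),
## 58 queen-removal individuals, 50 planted caste genes among 500
ds  <- simulateDataset(simulationConfig(n_genes = 500, n_informative = 50,
                                        n_age_genes = 50, seed = 7))
sel <- trainCasteClassifier(ds$se, repeats = 5, stopSize = 100, seed = 7)
sel
#> SelectedModel: 104 caste-informative genes; CV MSE = 0.02094 (iteration 397)

report <- classifySamples(sel, ds$se)
report
#> ClassificationReport: 96 samples
#>           group  n       mean          sd        min       max
#>           queen 26 0.90805770 0.023574750 0.89947318 1.0042174
#>  control_worker 12 0.09957101 0.001620378 0.09445545 0.1003853
#>         qr_day3 24 0.37055984 0.147025637 0.16197772 0.7276895
#>        qr_day12 34 0.42172718 0.157126079 0.19726703 0.7285831
```

Training castes pin to their labels (queens ≈ 0.91, workers ≈ 0.10 — within
the ε = 0.1 tube of 1 and 0), while queen-removal individuals spread over
intermediate values. Their estimates track the simulator's latent caste
state (Spearman ρ = 0.91 here), and the selected gene set recovered all 50
planted caste genes while overlapping the planted *age* genes no more than
chance (hypergeometric p = 0.997):

```r
compareGeneSets(sel, intersect(ds$truth$age_genes$gene, sel@universe))
#> OverlapResult: |A|=104 |B|=50 overlap=4 of 500; Jaccard = 0.027, hypergeometric p = 0.997
```

The full pipeline — simulate/read, filter (>20 counts per group), queenness
logistic model, train, classify, statistics, DE stand-in, JSON summary and
manifest — runs from a YAML config:

```r
cfg <- readPipelineConfig(system.file("config", "synthetic-demo.yaml",
                                      package = "casteSVM"))
runAll(cfg)   # writes TSV/JSON artifacts + manifest under cfg$outdir
```

Identical configurations produce byte-identical artifacts.

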