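Package: casteSVM
Title: Transcriptomic Caste Classification by Support Vector Regression
    with Recursive Feature Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies caste-associated brain gene expression in primitively
    eusocial insects from bulk RNA-seq count matrices. Trains a continuous
    caste classifier (epsilon-insensitive support vector regression, radial
    kernel) on queen and worker transcriptomes, selects caste-informative
    genes by recursive feature elimination with repeated threefold
    cross-validation, scores phenotypically intermediate individuals sampled
    after experimental queen removal, and links classifier estimates to
    phenotype (queenness, ovarian development, dominance, age) through linear
    models and gene-set overlap statistics. Includes a seeded negative-
    binomial simulator of the queen-removal study design so the whole
    pipeline is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
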