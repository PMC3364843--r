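Package: methylBench
Title: Benchmarking Feature Selection, Classification and Dimensional
    Reduction for Infinium DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A resampling framework for comparing statistical analysis
    strategies on Illumina Infinium-style DNA methylation matrices.
    Provides beta-value and M-value quantification from probe intensities,
    per-CpG association statistics (pooled two-sample t, simple linear
    regression, empirical-Bayes moderated t, Storey q-values), three
    feature-selection procedures (no filtering, variance filtering and
    supervised principal components), positive-predictive-value evaluation
    over repeated balanced train/test partitions, phenotype prediction with
    supervised principal components, penalized regression and support
    vector regression scored by the concordance index, and unsupervised
    modelling by singular value decomposition versus non-negative matrix
    factorization with deterministic NNDSVD initialization. A synthetic
    data generator with controllable effect size and signal strength
    emulates the heteroscedastic structure of beta-valued methylation data
    so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
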