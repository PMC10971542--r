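Package: scDEbench
Title: Benchmarking Differential Expression Analysis Under Small Biological
    Replication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-group single-cell RNA-seq-like count matrices from a
    compound Poisson-Gamma (Tweedie) model with known differentially expressed
    genes, scores genes with six differential-expression statistics (Welch t,
    Wilcoxon rank-sum, negative-binomial Wald with median-of-ratios size
    factors, empirical-Bayes moderated t, SAM-style regularized t, and an
    entropy-based DEF statistic), evaluates calls and rankings against ground
    truth (TPR, FPR, FDR, F1, Mean-Rank, MRSR, ROC/AUC), and combines the
    metric panel into composite method scores with the entropy weight method.
    Designed to study how these methods behave with 2 to 5 biological
    replicates per group.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
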