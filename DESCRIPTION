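Package: normbench
Title: Bias-Variance Evaluation of Post-Summarization Expression
    Normalization Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how post-summarization normalization procedures
    for log2 gene expression matrices (global mean-centering, fractional-rank
    replacement, quantile normalization, the delta-sequence pairing method,
    and surrogate variable analysis) trade variance reduction against induced
    bias in two-group differential expression analysis.  Provides per-gene
    two-sample tests (pooled t, empirical-Bayes moderated t, Wilcoxon
    rank-sum, and an N-statistic permutation test), Bonferroni and
    Benjamini-Hochberg adjustment, closed-form and Monte-Carlo predictors of
    normalization-induced bias and variance under an equicorrelated
    random-effect model, simulators for that model and a resampling simulator
    seeded by a synthetic expression matrix, and an evaluation harness that
    scores normalization x test x adjustment strategies by true and false
    positive counts and ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
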