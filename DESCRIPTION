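Package: metaboselect
Title: Biomarker Discovery for Targeted Serum Metabolomics via PLS-DA,
    Random-Forest Backward Selection and Monte Carlo Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for two-class biomarker discovery in
    targeted metabolomics feature tables (samples by metabolites, nonnegative
    peak areas): per-batch root-mean-square normalization, log transform and
    pareto scaling; NIPALS partial least squares discriminant analysis with
    variable-importance-in-projection (VIP) ranking; univariate ROC analysis
    with direction calls; sequential backward selection driven by random-forest
    out-of-bag error; and Monte Carlo cross-validation producing marker rank
    frequencies, importance scores, test-AUC distributions and composite ROC
    curves. Includes a synthetic-cohort generator with planted differential
    markers, multiplicative batch effects and log-normal noise, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
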