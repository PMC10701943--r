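Package: batchEB
Title: Empirical Bayes Batch Effect Correction for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Location-scale empirical Bayes batch effect correction for
    log-scale expression matrices (parametric and non-parametric posteriors,
    covariates, reference-batch and mean-only modes) and a negative binomial
    GLM plus quantile-matching corrector for raw RNA-Seq counts with native
    Cox-Reid dispersion estimation. Includes a synthetic data generator with
    known batch structure, residual-batch-effect diagnostics, TSV/CSV readers
    and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
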