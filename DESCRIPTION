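Package: methgxe
Title: Region-Based Blood Methylation EWAS with Gene-Environment Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified, region-based epigenome-wide association analysis of
    blood DNA methylation for early-stage Parkinson's disease, built as a tested,
    reusable pipeline. Calls co-methylated regions (CMRs) from array probes,
    summarizes them by per-sample median beta, balances cases and controls with
    probit propensity scores and full-matching weights, fits weighted
    Huber-regression EWAS models with Benjamini-Hochberg adjustment and
    permutation enrichment, quantifies cross-cohort replication, and ranks
    genotype/exposure model families (G, E, G+E, GxE) by AIC with Rubin's-rules
    pooling over multiply-imputed exposures. Includes a seeded synthetic-cohort
    generator with planted effects for ground-truth validation and power
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
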