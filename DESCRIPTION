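Package: pgxresponse
Title: Pharmacogenetic Drug-Response Phenotypes from Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to emulate drug-response cohorts from longitudinal electronic
    health records and study their pharmacogenetics. Provides a synthetic
    generator for prescription streams, biomarker trajectories and genotypes
    under an explicit longitudinal phenotype model; a quality-control cascade
    that reconstructs medication regimens (treatment start, switches,
    prescription regularity, co-medication rules) and selects baseline and
    post-treatment measures; absolute and log-relative drug-response
    phenotypes with covariate residualization and inverse-normal
    transformation; per-variant and polygenic-score association under the
    correct (unadjusted) and biased (baseline-adjusted) change-score models;
    and a closed-form plus Monte-Carlo analysis of the bias induced by
    adjusting biomarker differences for baseline levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
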