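Package: qvburden
Title: Rare Qualifying-Variant Burden Analysis of Red Blood Cell Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-set collapsing analysis of rare high-impact
    (qualifying) variants in small exome-sequenced cohorts, with an emphasis
    on red blood cell related phenotypes in critically ill patients.
    Implements qualifying-variant selection from annotated variant tables
    (consequence class, population allele frequency, cohort allele-count
    caps), variant spectrum summaries, gene-set (GMT) handling, per-person
    burden profiles under the dominant model, exact and asymptotic stratified
    Cochran-Mantel-Haenszel association tests with Mantel-Haenszel odds
    ratios and Robins-Breslow-Greenland confidence intervals, exome-wide
    single-variant scans with QQ/Manhattan summaries, longitudinal complete
    blood count endpoint extraction and anemia grading, nonparametric group
    comparisons, and multiple linear regression of RBC endpoints on clinical
    and genetic covariates with standard diagnostics and Benjamini-Hochberg
    false discovery rate screening. A synthetic-cohort simulator with known
    ground truth supports end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    car
Config/testthat/edition: 3
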