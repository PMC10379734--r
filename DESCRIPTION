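Package: deprpgs
Title: Polygenic Scores and Social Factors for Depression Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for candidate-panel polygenic score (PGS)
    analysis of quantitative depression scores in population cohorts:
    variant quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, linkage-disequilibrium proxy pruning),
    per-SNP covariate-adjusted additive association, weighted and
    unweighted PGS construction with negative-effect allele recoding,
    harmonization of external GWAS summary-statistic weights, nested
    linear regression models with adjusted r-squared variance
    decomposition, and AIC-based backward elimination of social
    predictors.  Includes a synthetic cohort generator emulating the
    genetic and social structure of a young-adult higher-education
    cohort (BDI-II depression outcome, Parental Bonding Instrument
    categories, family income and maltreatment flags) so that every
    stage of the pipeline is testable without access to individual-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
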