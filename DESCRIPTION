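Package: msprisk
Title: Polygenic Risk Score Deciles and Lifetime Risk of Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction of polygenic risk scores (PRS) from GWAS
    summary-statistic weights, with allele harmonization against genotype
    data; genotype quality control (call-rate filters, exact test of
    Hardy-Weinberg equilibrium, method-of-moments identity-by-descent
    relatedness filtering); control-based PRS decile assignment and
    sex-specific lifetime-risk estimation per decile in a birth-year
    cohort, including cumulative risk-by-age curves and "1 in N"
    rendering; and Cox proportional-hazards associations between the PRS
    and disease-course outcomes with principal-component adjustment and
    Benjamini-Hochberg correction. A seeded synthetic-cohort generator
    emulating a population-based multiple-sclerosis birth cohort makes
    the whole pipeline testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
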