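Package: snpmdr
Title: Case-Control SNP Association and Multifactor Dimensionality Reduction
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for single-nucleotide-polymorphism (SNP)
    case-control association studies on small genotyping panels: cohort
    input/output (delimited tables and VCF), genotyping quality control
    (call rates, high-missingness subject removal, ancestry-based
    inclusion, duplicate concordance), contingency-table association
    statistics (odds ratios with Woolf confidence intervals, chi-square
    homogeneity, Cochran-Armitage trend tests, covariate-adjusted
    logistic regression), and a from-scratch multifactor dimensionality
    reduction (MDR) engine with stratified cross-validation and
    permutation testing.  Ships a synthetic-cohort generator calibrated
    to a published 8q24 prostate-cancer case-control study in men of
    African descent (195 cases, 531 controls, seven SNPs), so that every
    stage of the pipeline is testable without access to subject-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    withr
Config/testthat/edition: 3
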