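Package: semgreml
Title: Latent Factor Models and GREML Variance Components for Symptom-Level
    Genetic Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-level pipeline linking psychiatric symptom
    questionnaires to genome-wide genotype data. Builds disorder-specific
    symptom scores and residualizes them on covariates, fits exploratory and
    confirmatory latent factor models (including hierarchical, bifactor
    "residual", and four-factor structures) by full-information maximum
    likelihood under missing data, extracts factor scores, and estimates SNP
    heritability and genetic correlations of the latent factors by univariate
    and bivariate average-information REML on a genomic relationship matrix,
    with a closed-form power calculator for bivariate GREML designs. Includes
    a synthetic-data generator with known latent and genetic ground truth so
    every stage is testable end to end, plus readers and writers for PLINK 1
    binary genotypes and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
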