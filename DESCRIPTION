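Package: modyscreen
Title: Family-Based Screening of MODY Variants in Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening maturity-onset diabetes of the young (MODY)
    variants in family-based cohorts. Implements ADA-rule glycemic phenotype
    classification from longitudinal fasting plasma glucose, oral glucose
    tolerance test and medication records; pedigree construction with
    relationship-degree queries and autosomal-dominant transmission
    assessment; two variant-filter pipelines (a known pathogenic/likely
    pathogenic screen and a candidate-discovery pipeline over cohort minor
    allele frequency, sequencing depth, CADD deleteriousness and disease
    penetrance); carrier, penetrance, prevalence and genetic-spectrum
    statistics; and a synthetic family-cohort generator (pedigree simulation,
    Mendelian gene dropping, penetrance-parameterised phenotypes) including a
    deterministic fixture cohort for end-to-end validation. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
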