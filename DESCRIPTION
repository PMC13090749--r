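Package: ednacongr
Title: Congruence of Taxonomic Assignments in Riverine Fish eDNA Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the congruence between independently produced taxonomic
    assignments of riverine fish environmental DNA (eDNA) metabarcoding datasets.
    Provides hierarchical local-species-pool correction (basin, country,
    continent), reference-database coverage auditing at species and genus
    resolution, four-category species-identity classification with shared-species
    and shared-read overlap statistics, from-scratch distance-based permutation
    tests (PERMANOVA, ANOSIM, multivariate dispersion, db-RDA, NMDS on Jaccard
    distances), and the explanatory regression stages (beta regression for
    overlap proportions, negative-binomial and beta mixed models via 'glmmTMB').
    Includes a synthetic multi-dataset community generator with ground truth for
    parameter-recovery testing, synonym-table name harmonization, and tabular
    readers/writers for whole collections.
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
    glmmTMB,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
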