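Package: epibrom
Title: Functional-Group Inference for Epiphytic Bromeliads from Leaf Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait-based inference of epiphytic bromeliad functional groups.
    Compiles species-by-trait tables with allometric gap-filling (leaf area
    from leaf length and width, tank capacity from leaf area, photosynthetic
    pathway from leaf carbon isotope signature), imputes remaining gaps under
    a multivariate Brownian-motion model on a phylogeny with a genus-mean
    fallback, applies log10/offset/rescale transformations, clusters species
    and traits by Ward's minimum-variance method, validates groups with a
    discriminant analysis based on squared Mahalanobis distances, assigns
    species to five functional groups (C3 tank, CAM tank, shallow tank,
    pseudobulb, nebulophyte) with a deterministic rule engine, and compares
    trait and climate distributions across groups with nonparametric tests
    and compact letter displays. Includes a seeded synthetic-data generator
    (phylogeny, archetype trait tables with missingness, occurrence-climate
    records) so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
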