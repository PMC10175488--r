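Package: icstools
Title: Infant Gut Community State Types, Strain Tracking and Enzymatic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising infant gut microbiomes from species-level
    relative-abundance profiles: selection of core species by prevalence and
    major-player criteria, discovery and naming of Infant Community State Types
    (ICSTs) by hierarchical clustering with ordination and permutation support,
    strain-level Population Subspecies (PS) tracking through species- and
    strain-specific canonical k-mer databases with coexistence statistics, and
    clustering of enzymatic (EC number) profiles with silhouette-based model
    selection and multivariable compound-level association. Includes a fully
    seeded synthetic-data generator (communities, strain genomes, reads, EC
    matrices) so every stage of the pipeline can be exercised and validated
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    vegan,
    cluster,
    mclust,
    stats,
    utils,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
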