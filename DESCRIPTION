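Package: bhmeta
Title: Meta-Analysis of Buchwald-Hartwig Coupling Reaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for curating and analysing corpora of
    Pd-catalysed C-N cross-coupling (Buchwald-Hartwig) reaction records:
    structure normalisation and template filters, rule-based reagent role
    assignment (solvent/base/ligand/metal source) with ligand extraction
    from defined Pd complexes, reactive-site detection and substrate
    classification via substructure matching with a tautomer fallback,
    InChI-keyed cross-source deduplication, condition cheatsheets ranked
    by median yield, a Pareto-front ligand recommender, and corpus-level
    trend statistics (bootstrap yield medians, yield-spike quantification,
    cumulative reagent coverage, Zipf frequency-rank fits). Includes a
    seeded synthetic corpus generator with ground truth for recovery
    tests, standing in for licensed reaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
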