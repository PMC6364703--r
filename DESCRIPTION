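Package: dielfba
Title: Multi-Phase Diel Flux Balance Analysis for Phototroph Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds periodic multi-phase flux balance models of phototrophic
    metabolism by replicating a base genome-scale metabolic model into a cyclic
    sequence of time point models linked by unidirectional metabolite-transfer
    reactions. Solves the biomass maximisation, transfer-minimising parsimonious
    FBA, and flux variability analysis cascade; scales reaction bounds from
    time-resolved transcriptomes (E-flux with gene-protein-reaction min/max
    rules); supports a nitrogenase/oxygen mutual-exclusion mixed-integer
    extension for diazotrophy; and provides downstream analyses including
    active-bound detection, flux control coefficients, metabolite-metabolite
    rank correlation, and category-wise transfer-flux aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) for the
    HiGHS linear/mixed-integer solver backend.
Config/testthat/edition: 3
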