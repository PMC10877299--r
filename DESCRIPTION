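Package: topoqspr
Title: Degree-Based Topological Indices and QSPR Modelling of Drug-Like
    Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fourteen degree-based topological indices (Zagreb
    family, atom-bond connectivity, Randic, harmonic, forgotten,
    geometric-arithmetic, sum-connectivity, inverse-sum and symmetric
    division degree) from hydrogen-suppressed molecular graphs via their
    degree-pair edge partitions, and fits univariate linear
    quantitative structure-property relationship (QSPR) models of
    physicochemical properties on each index.  Ships a curated study
    dataset of sixteen anti-hepatitis drugs (structures, property
    tables with uncertainties and missing cells, and the published
    index tables), a seeded generator of chemical-like bounded-degree
    graphs with linear-plus-noise synthetic properties for calibration,
    and report builders that reproduce per-index regression parameter
    tables, the correlation comparison matrix and best-descriptor
    rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
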