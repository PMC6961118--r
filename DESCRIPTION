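Package: thetascreen
Title: Phenotypic Divergence Scoring for Multi-Cell-Line Morphological Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing multi-cell-line Cell Painting screens: reading
    CellProfiler-style per-cell feature tables and plate maps, image-level
    quality control, median aggregation to image and well profiles, redundancy
    and variance feature selection, plate-wise DMSO-referenced normalization,
    a shared principal-component phenotype space centred on the negative
    control, l1-distance activity calling, multivariate Z'-factor assay
    quality, theta comparative cell scoring (TCCS) of angular phenotype
    divergence between cell-line pairs, and rank-product ordering of
    compound/cell-line-pair hits across replicates. A synthetic screen
    generator with known ground truth makes every stage testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
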