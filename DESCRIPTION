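Package: parityNiche
Title: Climatic Niche Comparison of Oviparous and Viviparous Lizard Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and compares the realized climatic niches of
    oviparous and viviparous clades of the Eurasian common lizard
    (Zootoca vivipara). Derives window-specific bioclimatic variables
    from monthly temperature and precipitation rasters, builds a
    background-calibrated principal component ordination of climate
    (PCA-env) with kernel occupancy surfaces on a 100 x 100 grid,
    computes Schoener's D niche overlap with permutation niche
    similarity and equivalency tests, discriminates parity modes with
    Gini classification trees (surrogate splits, 10-fold
    cross-validation, 1-SE pruning, impurity-based variable
    importance), and maps the observed differences in climatic
    variability and average temperature onto the cold-climate,
    maternal-manipulation and selfish-mother hypotheses for the
    evolution of viviparity. A synthetic-world generator produces
    smooth monthly climate fields and clade-structured occurrences so
    the whole pipeline is testable without climate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mgcv,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
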