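Package: endoface
Title: Global-to-Local Facial Endophenotypes from Dense 3D Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for defining and genetically dissecting facial
    endophenotypes from dense 3D landmark data. Implements symmetrization
    and generalized Procrustes alignment of corresponded landmark
    configurations, partial least squares residualization on covariates,
    data-driven facial segmentation by hierarchical spectral clustering of
    an Escoufier RV similarity matrix, per-segment principal component
    models with Horn's parallel analysis, one-component PLSR contrast
    traits with permutation testing and cosine-distance scoring, effective
    numbers of independent tests (Li-Ji), quantitative-trait single-SNP
    association with inverse-variance-weighted meta-analysis and distance
    clumping, and polygenic risk scores with LD clumping and threshold
    scans. A synthetic-data module generates landmark cohorts, linked
    genotypes and discovery summary statistics with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    vegan,
    withr
Config/testthat/edition: 3
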