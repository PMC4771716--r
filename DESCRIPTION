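Package: memscale
Title: Multiscale Spatial Eigenfunction Analysis of Species Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose spatial patterns in multi-species abundance
    tables across scales using Moran's Eigenvector Maps (MEMs) built on a
    Gabriel neighbour graph. Provides Hellinger and chi-square community
    transformations, principal component analysis, redundancy analysis and
    partial residual ordination, smoothed scalograms with a permutation test
    on the maximal scale component, forward selection of explanatory
    variables with a double stopping criterion, adjusted R-squared variation
    partitioning for two or three sets of predictors, and a seed-reproducible
    synthetic-data generator emulating a regional insect survey with
    temperature gradients interpolated from weather stations, multi-buffer
    land-use composition, and overdispersed counts with a hard thermal limit
    for an invasive species.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
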