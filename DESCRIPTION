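Package: healthineq
Title: Composite Health-Inequality Indices and Spatial Analysis for Small Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted-sum (WSA) composite indices of health-inequality
    determinants and health condition for small administrative regions, and
    analyses them in space and time: min-max normalization with maximize or
    minimize criterion directions, category and aggregate indices on the [0,1]
    utility scale, Pearson correlation matrices among category indices, paired
    Wilcoxon signed-rank tests of temporal change, Ward hierarchical clustering
    of regional index profiles with z-score cluster signatures, local Moran's I
    (LISA) with conditional-permutation inference on contiguity weights derived
    from region polygons, Fisher-Jenks natural-breaks classification, bivariate
    high and low class shares, and a synthetic panel generator with controlled
    inter-category correlation, temporal drift, spatial autocorrelation and
    plantable hotspots for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
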