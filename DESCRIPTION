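Package: mortfda
Title: Functional Data Analysis and Clustering of Mortality Age-at-Death Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing life-table death distributions (d_x curves) as
    functional data. Curves are represented by penalized B-spline expansions with
    generalized cross-validation smoothing, summarised by functional principal
    component analysis (mean, eigenfunctions, scores, harmonic-variation curves),
    and grouped by three functional clustering methods: two-stage k-means on
    basis coefficients, hierarchical clustering on an FPCA-score semimetric, and
    a functional latent mixture model fitted by EM with BIC-based selection of
    the number of clusters. Includes a reader for Human Mortality Database style
    period life tables, a synthetic-cohort generator with controllable infant,
    premature and old-age mortality components, and an end-to-end pipeline with
    tidy outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
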