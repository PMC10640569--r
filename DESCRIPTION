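Package: netpercolate
Title: Percolation-Based Robustness of Weighted Brain Networks Across
    Densities, with Function-on-Scalar Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates in silico attacks (random, betweenness- and
    eigenvector-centrality targeted) on weighted connectomes across a dense
    grid of proportional thresholds, extracts the second-largest-component
    percolation point at each density, and models the resulting
    percolation-point-by-density functions with penalized function-on-scalar
    regression (cubic P-splines) to test covariate effects such as age, sex,
    handedness and mean node distance. Includes narrowband weighted phase lag
    index (wPLI) connectivity estimation from multichannel oscillatory
    recordings via Slepian multitapers, GCV-penalized B-spline smoothing for
    functional quality control, and a synthetic cohort generator producing
    weighted graphs whose hub concentration shifts with a continuous age
    covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    mgcv,
    Rcpp,
    jsonlite,
    yaml,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
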