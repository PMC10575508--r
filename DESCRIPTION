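Package: corridorscape
Title: Habitat Suitability, Least-Cost Corridors and Circuit-Theory
    Connectivity Across Protected-Area Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling functional landscape connectivity for
    wide-ranging wildlife across protected-area (PA) networks. Implements
    an accuracy-weighted ensemble of presence/pseudo-absence species
    distribution models with AUC evaluation, jackknife variable
    importance and Jenks natural-breaks suitability classing;
    transformation of habitat suitability into landscape resistance;
    least-cost corridor extraction between PA pairs with cost-weighted
    distance (CWD), CWD:EUD and CWD:LCP corridor-quality ratios and
    corridor truncation; circuit-theory pinch-point (current-density)
    mapping and current-flow link centrality; land-cover change
    accounting with confusion-matrix accuracy and Cohen's kappa; and
    corridor validation against transect and interview data. A synthetic
    landscape generator with known ground truth (correlated covariate
    fields, expanding cropland, PA polygons, presence points, transects
    and sighting reports) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    xgboost,
    ranger,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
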