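Package: tlsbiomass
Title: Tree Volume and Above-Ground Biomass from Terrestrial Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for deriving structural metrics and above-ground
    biomass (AGB) of large conifers from single-tree terrestrial laser
    scanning (TLS) point clouds. Measures tree height, diameter at breast
    height (DBH) by least-squares circle fitting, functional DBH (fDBH) by
    alpha-shape cross-section area, and diameter at top of buttress (DTB);
    estimates whole-tree volume, trunk/branch decomposition and woody
    surface area with a cylinder-based quantitative structure model (QSM)
    ensemble; converts volume to AGB through wood density and a bank of
    published allometric models with Monte-Carlo propagation of
    geometric-fit uncertainty; aggregates to plot-level AGB density; and
    fits new power-law allometries to TLS-derived data. Includes a
    synthetic-forest generator producing fluted, buttressed stems with
    branch whorls, range noise and occlusion, together with analytic
    ground-truth volumes, so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
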