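Package: valliES
Title: Ecosystem Service Capacity and Flow Assessment for Managed
    Coastal Lagoon Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit assessment of ecosystem-service (ES)
    capacity and flow for the diked, privately managed sub-basins
    ("valli da pesca") at the edges of the Venice lagoon. Provides a
    land-cover raster data model with patch geometry, the eight
    landscape indicators used to characterise the units (class-area
    ratios, saltmarsh perimeter/area, Shannon diversity and evenness),
    nine ES capacity/flow indicators across the regulating,
    provisioning and cultural categories, min-max normalisation and
    category aggregation, and the nonparametric group-comparison
    workflow (Shapiro-Wilk/Bartlett routing, Kruskal-Wallis with Dunn
    post-hoc or ANOVA with Tukey HSD, significance letters, Spearman
    correlogram). A seed-deterministic synthetic-scenario generator
    emulates the 31-unit study system for testing and method
    exploration, since the underlying management records are private.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
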