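Package: blowdownr
Title: Wind-Throw Disturbance Gradients from Spectral Unmixing and
    Forest Inventory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies wind-throw (blowdown) disturbance intensity in
    tropical forest from pre/post-storm multiband reflectance: linear
    spectral mixture analysis into green-vegetation, non-photosynthetic
    vegetation (NPV) and shade fractions, shade normalisation, change in
    NPV (dNPV), a calibrated linear dNPV-to-tree-mortality model with a
    zero floor, connected-component gap delineation, and area-weighted
    per-plot disturbance metrics. Relates field-census structure
    (density, basal area, DBH distributions, wood density, resprouters,
    pioneer fractions) and community composition (importance values,
    Shannon diversity, hypergeometric rarefaction, NMDS ordination,
    Mantel tests, genus response splines) to the resulting mortality
    gradient. Ships a synthetic landscape and stem-table generator with
    known ground truth so the whole pipeline is testable end to end.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
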