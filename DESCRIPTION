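Package: ch4path
Title: Compositional, Thermodynamic and Isotopic Attribution of Dissolved
    Methane in Groundwater
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for attributing dissolved methane in
    groundwater samples to microbial production and consumption pathways
    (CO2-reduction methanogenesis, acetoclastic methanogenesis, sulfate
    reduction, anaerobic oxidation of methane). Combines sequential-binary-
    partition isometric log ratios of reaction-species activities, Gibbs
    free energy of the microbial redox reactions with per-electron
    normalization, carbon and hydrogen isotope fractionation factors with
    Rayleigh fractionation curves, a Davies-equation activity model,
    left-censored (below detection limit) concentration imputation, and a
    synthetic-catchment generator emulating coal seam gas and alluvial
    aquifer hydrochemistry for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
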