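Package: heatvuln
Title: Two-Stage Heat Vulnerability Analysis from Case-Crossover Odds Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates county-level associations between warm-season heat
    exposure and acute morbidity (emergency department visits and hospital
    admissions) using a semi-symmetric bidirectional time-stratified
    case-crossover design with an internally implemented conditional logistic
    likelihood, then relates the resulting odds ratios to county demographic
    and socioeconomic variables through correlation pruning, backward stepwise
    AIC selection, and aspatial or maximum-likelihood spatial lag regression
    with Moran's I diagnostics. Includes heat index exposure metrics,
    population-weighted exposure aggregation, and a seeded synthetic-data
    generator that emulates warm-season weather, correlated area covariates,
    lattice county adjacency, and Poisson-thinned health events with known
    ground truth, so the full pipeline is testable without restricted health,
    weather, or census inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    ape,
    optparse,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
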