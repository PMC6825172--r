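Package: spongeimpact
Title: Bottom-Trawling Impact Assessment for Deep-Sea Sponge Grounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline to quantify the impact of bottom trawling
    on deep-sea sponge grounds. Builds sponge biomass surfaces from
    research-vessel catch records by two routes (a 5 x 5 km grid-cell
    estimator with closure-aware merged strata and focal infilling, and a
    random-forest distribution model on environmental covariates),
    reconstructs commercial trawl tracks and swept-area footprints from
    vessel-position pings, accounts for sponge removal under a worst-case
    100 percent removal assumption, simulates directed trawling inside
    fishery closures, upscales Geodia barretti physiological rates
    (filtration, respiration, carbon consumption, nitrogen fluxes) to
    regional ecosystem function with uncertainty, and monetizes the lost
    filtration service by replacement cost against a wastewater-treatment
    plant. A seeded synthetic-seascape generator supplies depth-structured
    patchy biomass fields, survey tows, vessel trajectories and closure
    polygons so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
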