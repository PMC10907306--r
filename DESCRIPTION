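Package: ewcdr
Title: Soil-Based Carbon Dioxide Removal Accounting for Enhanced Rock Weathering Field Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mass-balance accounting of basalt weathering in amended cropland
    soils using an immobile trace element (titanium). Computes the basalt mass
    fraction of treated soil by two-endmember mixing, cation (Ca, Mg) loss from
    the applied rock, and the time-integrated potential carbon dioxide removal
    (CDR) under Urey-reaction stoichiometry, with first-order Gaussian error
    propagation validated by a Monte-Carlo oracle. Includes the agronomic
    budget calculations used alongside such trials (nutrient pools, nitrogen
    use efficiency, phosphorus and potassium release from immobile-element
    ratios in recovered rock grains, grain cation export), a yield-value
    extrapolation for the US Corn Belt, and a randomized-block field-trial
    simulator with known truth for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
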