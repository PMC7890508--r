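Package: reltrade
Title: Relation-Driven Agent-Based Global Food Trade and Nutrition Security Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates global food trade as a relation-driven agent-based
    model in which country agents rank and match trade partners by GDP per
    capita, geographic distance, historic trade and endogenously emerging
    trade relationships. Realized trade plus domestic production yields
    per-capita macro- and micronutrient intake, which is classified against
    demographically weighted requirements to assess national nutrition
    security under trade-saturation scenarios. Includes a synthetic world
    generator emulating food-balance-sheet structure, a round-based
    offer/acceptance market engine with per-round transaction caps, a
    nutrition pipeline accounting for household waste, edibility and flour
    fortification, and a multi-objective calibration harness (Latin
    hypercube design, exponential weight transform, volume and partner
    match rates, Pareto-front selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    geosphere,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
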