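Package: eaglewinter
Title: Winter Climate, Salmon Carcass Decay, and Bald Eagle Bioenergetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline linking projected winter climate to the
    food supply and energy demand of bald eagles overwintering on Puget
    Sound chum salmon runs. Provides a seeded synthetic winter weather
    generator with day/night partitioning by photoperiod, a
    temperature-driven exponential carcass decomposition model fitted to
    published decay observations, a chum salmon run and carcass-biomass
    simulator, a daily eagle food-consumption bioenergetics model, and a
    factorial scenario grid (climate models x sites x decades x years)
    that emits tidy monthly and seasonal summary tables with decade
    contrasts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
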