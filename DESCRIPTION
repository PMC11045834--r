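Package: trichosim
Title: Spatial Monte Carlo Simulation of Egg-Parasitoid Releases Against
    the Sugarcane Borer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic, spatially explicit simulation of augmentative
    biological control of the sugarcane borer (Diatraea saccharalis) by
    inundative releases of the egg parasitoid Trichogramma galloi.
    Insect phenology is driven by degree-day accumulation, adult life
    spans are Normal, daily fecundity and parasitism follow an
    exponentially declining oviposition rhythm, pests disperse by a
    truncated exponential kernel on a square-metre lattice and
    parasitoids search hosts within an action radius.  A scenario engine
    compares release strategies (parasitoid density per release versus
    number of weekly releases) over replicated Monte Carlo runs with
    common random numbers, confidence bands, larval-ratio series and
    fold-reduction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
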