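Package: aedesfuse
Title: Fusing Statistical Abundance Reconstructions with Mechanistic
    Models of Aedes aegypti Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a statistical reconstruction of adult female Aedes
    aegypti abundance to mechanistic population models. Provides a
    temperature-driven stage-structured ordinary-differential-equation
    model of the egg, larva, pupa and adult stages with quadratic
    density-dependent larval mortality; an inverse-calibration procedure
    that derives a non-negative, time-varying residual immature mortality
    rate so that the mechanistic model reproduces any target abundance
    series; a spatially explicit stochastic agent-based simulation with
    per-building immature stages and individual adult mosquitoes; and
    insecticide-spraying campaign models (ultra-low volume and targeted
    indoor residual spraying) together with summaries of their
    spatio-temporal and age-structure consequences. A synthetic-city
    generator emulates the required inputs (building map with zones,
    seasonal temperature series, separable space-by-time abundance
    surface) at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
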