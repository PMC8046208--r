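Package: sppsim
Title: Gridded Simulation of Grass-Pollen Rupture and Sub-Pollen Particle
    Transport for Thunderstorm-Asthma Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Eulerian simulator of airborne ryegrass pollen,
    pollen shells and sub-pollen particles (SPPs). Implements logistic
    emission-activity functions for relative humidity, precipitation and
    wind; eight pollen-rupture parameterisations (humidity thresholds,
    wind-speed functions, static electricity at low humidity, lightning
    counts, and on-plant mechanical rupture); a simplified tracer-transport
    core with upwind advection, implicit vertical diffusion and
    gravitational settling; synthetic meteorology generators emulating a
    dry gust-front thunderstorm and humid nights; and time-series
    evaluation (regression slope and Pearson correlation) against hourly
    pollen-trap observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
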