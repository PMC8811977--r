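Package: forestflux
Title: Spatially Explicit Gain-Loss Simulation of Forest Carbon Dynamics
Version: 0.1.0
Authors@R:
    person("forestflux", "developers", email = "forestflux@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, spatially explicit forest carbon simulator using
    the gain-loss (stock-flow) method. Tracks 14 live and dead-organic-matter
    carbon pools per grid cell on an annual timestep, with species growth
    driven by Von Bertalanffy merchantable-volume curves, net primary
    productivity schedules derived from reference stand simulations,
    temperature-dependent (Q10) decay of dead organic matter, climate-driven
    growth and decay multipliers, a dead-organic-matter spin-up under a
    historical fire regime, and a state-and-transition landscape model of
    land-use change and disturbance (wildfire severity classes, clearcut and
    selection harvest, insect mortality, urbanization, agricultural
    expansion, post-fire recovery, reforestation). Produces annual carbon
    accounts (NPP, Rh, NEP, NBP) by landscape stratum together with
    per-pool stock grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
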