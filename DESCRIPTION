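Package: tcbloom
Title: Diagnostics for Tropical-Cyclone-Driven Phytoplankton Blooms
Version: 0.1.0
Authors@R:
    person("Ocean", "Diagnostics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to diagnose the upper-ocean response to a tropical
    cyclone and attribute a lagged chlorophyll-a bloom to storm-enhanced
    cyclonic eddies. Implements wind-stress curl and Ekman pumping velocity
    on a spherical latitude/longitude grid, relative vorticity of surface
    current fields with box-averaged positive-vorticity summaries, buoyancy
    frequency and thermocline/mixed-layer depth from temperature/salinity
    profiles, cloud-gap-aware box-averaged time series with two-day
    compositing, and bloom-lag, fold-increase and sea-surface-cooling
    metrics. A bundled synthetic-data module generates every input the
    pipeline consumes (a translating parametric cyclone wind field, Gaussian
    cyclonic eddies in sea surface height with geostrophic currents,
    tanh-thermocline hydrographic profiles, and lagged cloud-masked
    chlorophyll fields) with known ground truth, so every stage is testable
    without external satellite, reanalysis or float products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
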