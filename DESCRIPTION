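Package: docprime
Title: Coupled Dissolved Organic Carbon Transport and Microbial Priming
    Simulation for Organic Soil Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coupled hydrological, physical, and biological
    processes that control real priming effects of dissolved organic carbon
    (DOC) inputs on soil organic carbon (SOC) decomposition in boreal forest
    organic horizons.  A one-dimensional advection-dispersion solver with
    two-site (equilibrium/kinetic) linear sorption moves DOC through a
    1-cm-layered soil column whose unsaturated hydraulics follow the
    Mualem-van Genuchten model; microbial biomass carbon drives SOC
    hydrolysis, DOC uptake, growth, death, and maintenance respiration under
    hourly temperature and moisture forcing.  Includes seeded synthetic
    forcing generators for two site archetypes (well drained and moderately
    well drained over permafrost), spin-up to equilibrium, paired
    pulse/no-pulse priming experiments, warming and no-transport
    counterfactuals, experiment grids over DOC input fraction, pulse period
    and necromass partitioning, and one-at-a-time parameter sensitivity
    analysis with a normalized-range sensitivity index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
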