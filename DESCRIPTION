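Package: seagrassdyn
Title: Dynamics of an Intertidal Seagrass-Lucinid Mutualism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a minimal ordinary-differential-equation
    model of a tropical intertidal seagrass bed coupled to sulfide-oxidizing
    lucinid bivalves. Seagrass detritus accumulates as sediment organic matter,
    whose anaerobic decomposition produces phytotoxic pore-water sulfide; the
    bivalve-bacteria consortium consumes sulfide and so buffers the seagrass
    against self-poisoning. The package integrates the model under scenarios
    with and without the mutualism, classifies the resulting dynamical regime
    (stable bed, damped oscillation, slow-fast limit cycle, collapse), scans
    mortality for the onset of cycles, runs per-parameter sensitivity analyses,
    generates stochastic ensembles over a mortality gradient, and applies
    kernel-density potential analysis to detect attractors and repellors in
    simulated shoot densities or remotely sensed vegetation indices. A seeded
    synthetic generator of NDVI-by-elevation datasets is included for testing
    the field arm of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
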