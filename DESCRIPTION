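Package: kpuu
Title: Unbound Brain-to-Plasma Partition Ratios from a Single In Vitro
    Blood-Brain-Barrier Experiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the unbound brain-to-unbound plasma concentration
    ratio (Kp,uu) of drug candidates from a single one-hour transwell
    experiment in an endothelial/glial co-culture model of the blood-brain
    barrier. Provides a forward simulator of two-compartment transwell
    transport, a classed model fit that extrapolates the one-hour
    donor/receiver concentrations to the constant-donor steady state,
    monolayer-integrity QC from a sucrose tracer, the reference fraction
    unbound calculations (equilibrium dialysis of plasma and diluted brain
    homogenate, and the brain-slice unbound volume of distribution with
    water-adhesion correction), in vivo translation utilities (residual
    blood correction, total-to-unbound ratio conversion, free-brain
    concentration-time profile prediction, microdialysis carrier-flow
    correction, fold-error comparison, efficacy coverage), paired-ratio
    concordance statistics, and a seeded synthetic-data generator for
    validating every estimator against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
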