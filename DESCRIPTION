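Package: organoflux
Title: Transport Modelling for Intra-Organoid Microfluidic Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates pressure-driven channel hydraulics, Darcy leakage
    flow and transient advection-diffusion through a time-saturating
    nanoporous membrane into agarose phantoms and spheroidal organoids,
    for 3D microfluidic intra-organoid delivery platforms. Provides a
    finite-volume solver for layered porous media in Cartesian and
    spherical geometry, derived transport metrics (steady-state time,
    interface flux, penetration depth), nonlinear least-squares
    calibration of the membrane saturation law against concentration
    profile time series, and a seeded generator of synthetic
    fluorescence and MRI-like profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
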