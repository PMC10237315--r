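Package: tebvflow
Title: Reduced-Order Fluid-Structure Interaction Analysis of Tissue-Engineered
    Blood Vessels on a Chip
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibration and simulation pipeline for perfused tissue-engineered
    blood vessels (TEBV) in microfluidic chips. Reduces uniaxial tensile tests
    to stress-stretch curves and fits a linear Hookean wall modulus; fits a
    shear-thinning power-law viscosity model to rheometer sweeps; simulates
    pulsatile perfusion of the compliant thick-walled vessel with a
    one-dimensional fluid-structure interaction model closed by the Lame
    thick-walled-cylinder tube law, with power-law wall friction and laminar
    velocity-profile reconstruction; and quantifies agreement between
    simulated and measured diameter waveforms, flow rates and cell-cluster
    velocities. Includes a seeded synthetic-data generator emulating every
    bench measurement the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
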