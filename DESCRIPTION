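Package: photosulfide
Title: Kinetic Modelling of Oxygenic and Anoxygenic Photosynthesis Under
    Sulfidic Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic kinetic model of the photosynthetic electron
    transport chain of a metabolically versatile cyanobacterium that switches
    between oxygenic and anoxygenic (sulfide-driven) photosynthesis.  The
    model couples photosystem II excitation, degradation and repair,
    sulfide inhibition of the oxygen-evolving complex, sulfide:quinone
    oxidoreductase kinetics feeding the plastoquinone pool, an optional
    second sulfide oxidase donating electrons downstream of plastoquinone,
    photosystem I turnover and NADPH-consuming carbon fixation.  The package
    simulates microsensor experiments (sulfide injections, light-dark
    shifts, DCMU treatments, photosynthesis-irradiance curves, diel cycles),
    extracts gross photosynthesis rates from sensor-style traces by the
    light-dark shift method, fits photosynthesis-irradiance curves, and
    calibrates the model to rate datasets, including discrimination between
    alternative sulfide-oxidation pathway variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
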