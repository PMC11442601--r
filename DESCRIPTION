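Package: pefros
Title: Reaction Kinetics of Electrogenerated Reactive Oxygen Species and
    Chemiluminescence in Pulsed-Electric-Field Treated Protein Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator and analysis toolkit for oxidative
    chemistry driven by pulsed electric fields (PEF) in protein solutions,
    with bovine serum albumin (BSA) as the model protein. Implements a
    mass-action reaction network for electrogenerated reactive oxygen
    species (hydroxyl and hydroperoxyl radicals, superoxide, hydrogen
    peroxide, singlet oxygen), Fenton iron cycling, antioxidant enzyme
    kinetics (superoxide dismutase, catalase) and protein oxidation up to
    light-emitting species, integrated with a stiff ODE solver over a
    three-compartment electrode-layer/bulk geometry. Companion closed-form
    electrophysics calculators (field strength, ohmic current,
    electromigration, Joule heating, current-rise thermometry, Faraday
    coulometry), a photomultiplier detector model with band-resolved
    quantum efficiency, a photon-count transient analysis pipeline
    (window integrals, replicate averaging, dose-response), Beer-Lambert
    assay calculators (Ellman sulfhydryl, Brady carbonyl), and a
    synthetic-data generator with Poisson counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
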