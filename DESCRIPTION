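Package: rxnkin
Title: Thermochemistry, Transition-State-Theory Rates and Microkinetic
    Modeling for Quantum-Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for turning quantum-chemistry frequency
    calculations into kinetic predictions. Parses XYZ geometries and
    ORCA-style frequency outputs; computes zero-point energies, thermal
    corrections, entropies, enthalpies and Gibbs free energies under the
    ideal-gas rigid-rotor harmonic-oscillator model (with optional
    low-frequency floors and quasi-RRHO interpolation); derives
    reference-based relative energies, activation and reaction energies
    and energy profiles over reaction networks; evaluates Eyring rate
    constants with standard-state conversions; and integrates mass-action
    microkinetic models with a stiff ODE solver to extract selectivities,
    apparent activation energies and reaction orders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
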