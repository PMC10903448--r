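Package: gatekin
Title: Binding and Permeability Kinetics for Calmodulin-Gated Water Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying calmodulin-dependent gating of
    aquaporin water channels reconstituted in proteoliposomes. Fits
    bi-exponential shrinkage kinetics from stopped-flow light-scattering
    traces and converts rate constants to osmotic water permeability (Pf);
    fits microscale thermophoresis (MST) dose-response curves with an exact
    one-to-one ligand-depletion model or a two-to-one cooperative
    partition-function model with automatic model selection; performs
    two-process global fitting of surface plasmon resonance (SPR) sensorgram
    sets (bi-exponential dissociation, then association with fixed off-rates)
    and derives equilibrium constants with a geometric-mean summary affinity;
    compares groups with a Z-test for population means. Includes seeded
    simulators for all three assay types so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
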