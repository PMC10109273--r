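Package: pulsephantom
Title: Design and Pulsatile Control of Multilayer Tissue-Mimicking Phantoms
Version: 0.1.0
Authors@R:
    person("Phantom", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing polydimethylsiloxane (PDMS) tissue-mimicking
    phantoms for photoplethysmography (PPG) applications and for driving their
    pulsatile artificial blood vessels. Covers extraction of Young's modulus
    from tensile stress-strain curves and linear curing-agent calibration,
    thick-walled-cylinder (Lame) conversion of arterial pressure pulses into
    vessel-wall radial displacement, linear micropump voltage calibration and
    synthesis of discretised pump-voltage sequences replicating a target pulse,
    additive spectral modelling of absorbing and scattering dopants with
    non-negative least-squares recipe solving, Sellmeier dispersion fitting,
    and sub-pixel channel-diameter measurement from grayscale images. A seeded
    synthetic-data module generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
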