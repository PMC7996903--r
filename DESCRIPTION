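Package: bnctbeams
Title: Physical, Radiobiological, and Dosimetric Evaluation of BNCT Neutron Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and rank epithermal neutron beams for boron
    neutron capture therapy (BNCT). Implements the IAEA in-air figures of
    merit with compliance checking, multi-component RBE/CBE-weighted and
    ICRP-style equivalent dosimetry, dose-volume histograms, Poisson
    linear-quadratic tumor control probability (TCP), logistic normal-tissue
    complication probability (NTCP), uncomplicated tumor control probability
    (UTCP) maximized over irradiation time, and out-of-beam organ dose
    tables used as a safety criterion to select among candidate beams. A
    kernel-based synthetic beamline module generates beam-port spectra,
    radial flux profiles, in-phantom dose-component fields, and organ-dose
    inputs with the structure the analysis assumes, replacing Monte Carlo
    transport at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
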