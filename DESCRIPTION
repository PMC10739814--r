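Package: pgcam
Title: Compton-Camera Imaging of Boron Neutron Capture Prompt Gamma Rays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for prompt-gamma imaging of the
    boron neutron capture reaction with a stacked Si/CdTe Compton camera.
    Provides closed-form Compton kinematics and Klein-Nishina sampling, a
    calibrated detector response model (energy resolution and angular
    resolution measure), a seeded Monte-Carlo generator of list-mode two-hit
    events for configurable source scenes, the event-selection rules used for
    478 keV prompt-gamma imaging, photopeak spectroscopy with net/gross peak
    ratios, Compton-cone back-projection and list-mode maximum-likelihood
    expectation-maximization reconstruction on the target plane, and
    background-subtracted pixel-value-ratio contrast metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
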