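Package: cuffdrift
Title: Simulating Chronic Signal Drift and Classifier Update Strategies for
    Multi-Contact Nerve Cuff Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes multi-contact nerve cuff recordings of compound
    action potentials propagating along the tibial, peroneal and sural
    pathways of a rat sciatic nerve, using an analytic layered
    volume-conductor leadfield over a 56-contact cuff. Two chronic
    perturbations are simulated (encapsulation tissue growth between the
    epineurium and the cuff, and rotation of the cuff around the nerve),
    noisy spatiotemporal signatures are extracted and classified into the
    three pathways, and three classifier update strategies (baseline
    calibration, periodic recalibration, and confidence-thresholded
    self-learning) are compared over simulated time, including a
    training-frequency / initial-performance slope analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
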