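Package: aeromorph
Title: Drone-Based Photogrammetry of Megafauna with Measurement Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for drone-based photogrammetric morphometrics of large
    animals, particularly cetaceans. Converts pixel measurements to metric
    units via ground sampling distance, reads and filters collated
    image-measurement tables, and fits a Bayesian hierarchical
    measurement-error model trained on known-size calibration objects to
    produce posterior distributions for body lengths and widths across
    drones with different altimeters (barometer and/or LiDAR). Includes
    per-draw body-condition metrics (standardized widths, projected area,
    body volume, body area index), a hierarchical von Bertalanffy-Putter
    growth-curve sampler for repeated length measurements of individuals,
    two-stage multiple-imputation propagation of measurement uncertainty
    into downstream analyses, and a synthetic-data generator with known
    ground truth for calibration and validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
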