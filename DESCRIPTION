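Package: gaitspace
Title: Gait-Space Analysis of Multi-Legged Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing interleg coordination in multi-legged
    animals from dorsal-view tracked landmark time series. Estimates per-leg
    oscillation phases from standardized tarsus kinematics, embeds
    leg-coordination patterns as points on a non-Euclidean hypertorus gait
    space equipped with a quotient metric tensor, measures normalized
    distances to model gaits (alternating tetrapod, ablated tetrapod,
    modified tripod), and groups empirical gait patterns by hierarchical
    clustering with Ward linkage on precomputed gait distances. Also
    computes locomotor kinematics (speed, tortuosity, yaw, stride timing,
    duty factor), static-stability measures (support polygon, stability
    margins, leg spacing, range of motion), and generates fully synthetic
    trials with von Mises phase noise so the entire pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
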