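Package: cagetraj
Title: Trajectory and Activity Analysis for Capacitive Home-Cage Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing rodent movement recorded in digitally
    ventilated home cages whose floor carries a grid of capacitive
    electrodes sampled every 250 ms. Provides trajectory kinematics
    (displacement, velocity, acceleration, speed gating, regular-grid
    resampling), turn-angle and laterality statistics with polar binning,
    activity-event detection and centroid estimation from raw capacitance
    streams, circadian day/night aggregation with day-range pooling and
    long-format export for longitudinal modelling, and a seeded
    correlated-random-walk cage simulator with a forward sensor model so
    that every stage of the pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
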