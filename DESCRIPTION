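Package: tetherSMT
Title: Simulation and Bias Analysis for Single-Molecule Tracking in
    Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("tetherSMT", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of guest-molecule trajectories inside
    spherical biomolecular condensates, with and without whole-condensate
    Brownian rotation, and the matching single-molecule tracking analysis
    pipeline: time-averaged MSD curves, anomalous-exponent and motion-blur
    corrected apparent-diffusion fitting, rotation-referenced kinematics,
    nonparametric group comparison with Cliff's delta effect sizes, mask
    circularity, and paired tethered/untethered parameter sweeps that map
    when surface tethering of condensates is required for unbiased
    diffusion measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
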