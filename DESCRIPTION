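Package: iaa2d
Title: Induced-Acceleration Muscle Potentials for a Planar Four-Link Body Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An efficient induced-acceleration analysis for a sagittal-plane,
    four-link rigid-body model of the human body pinned at the foot. For any
    kinematic state the package computes each muscle's potential -- the
    whole-body centre-of-mass acceleration generated per Newton of muscle
    force -- along the vertical (support) and anteroposterior (progression)
    axes, using an analytic Lagrangian mass matrix, tendon-excursion moment
    arms from pluggable providers, and the centre-of-mass Jacobian. It
    enumerates the constrained sit-to-stand kinematic state grid, derives
    normalized foot-position and pelvis-height metrics, and runs rank-based
    inverse-normal / Pearson correlation analyses of potentials against
    kinematic modifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
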