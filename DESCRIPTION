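Package: pedrecon
Title: Reconstruction of Vehicle Collisions with Running Pedestrians
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for forensic reconstruction of car collisions with
    running pedestrians. A spring-loaded inverted pendulum (virtual leg)
    model generates a physically consistent periodic running gait at a
    commanded speed; cubic-spline limb planning and two-link inverse
    kinematics convert the centroid trajectory into per-joint angle and
    angular-velocity time series; the collision-moment pose initialises an
    articulated rigid-flexible multibody pedestrian model that is advanced
    through vehicle and ground contact with penetration-stiffness force
    curves, hysteresis and regularised Coulomb friction.  Head injury
    criterion (HIC), chest 3 ms clip and a long-bone bending-stress proxy
    are evaluated against tolerance limits, and throw, slide and
    rest-position metrics are reported for multi-case comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
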