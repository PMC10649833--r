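Package: reachkin
Title: Simulation and Kinematic Analysis of Poststroke Center-Out Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse horizontal center-out reaching
    in people with poststroke hemiparesis. Provides a seeded synthetic
    cohort generator emulating a 1-kHz exoskeleton recording of an
    8-target visually guided reaching task, per-trial kinematic metrics
    (dual-threshold movement-onset detection, movement time, path length,
    velocity-peak counting on zero-phase Butterworth-filtered speed, and
    anteroposterior/mediolateral displacement decomposition), trial
    qualification rules for movement-quality and movement-quantity
    analyses, and the group-level inference used in direction-dependence
    studies: three-way repeated-measures ANOVA with Mauchly's sphericity
    test and Greenhouse-Geisser correction, a linear mixed-effects model
    of the mediolateral displacement proportion, and paired t tests on
    clinical impairment scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
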