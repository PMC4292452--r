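Package: ipguidance
Title: Interaction-Pattern Analysis of Spatial Guidance Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling and analyzing goal-directed spatial guidance
    as a hierarchy of planning, perceptual guidance, and tracking control.
    Simulates closed-loop planar vehicle behavior with tau-coupled gap
    closure, extracts Interaction Patterns (equivalence classes of
    trajectory segments under subgoal sharing and planar rigid-motion
    symmetry), learns time-to-go functions by forward stepwise selection
    with cross-validation, predicts subgoal organization with a wavefront
    planner, and classifies operator gaze streams (fixation, saccade,
    smooth pursuit) against the attentional predictions of the model.
    Includes seeded synthetic-fixture generators for environments,
    trajectory ensembles, and gaze streams with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
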