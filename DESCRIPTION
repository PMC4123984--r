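Package: kinescore
Title: Automated Scoring of Upper-Limb Movement Impairment from Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 3D skeletal landmark trajectories of the upper limb into
    four physiological joint angles, segments repeated movements by
    correlation-template matching, and scores movement impairment as the
    coefficient of determination of paretic-arm trials reconstructed from the
    principal components of the averaged non-paretic movement. Includes the
    reliability machinery around the score: bootstrap estimation of the
    minimal number of movement repetitions, the number of human raters an
    automated score matches, per-rater intraclass correlation, regression of
    quantitative against clinical ordinal scores with analytic power, and
    leave-one-subject-out decoding. A synthetic-data module generates
    ground-truth kinematics, impairment signatures, capture noise for
    high-rate and low-cost systems, and noisy ordinal rater panels, so the
    whole pipeline is testable without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
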