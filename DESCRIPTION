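Package: flycourt
Title: Machine-Assisted Spatiotemporal Analysis of Drosophila Male
    Courtship Around a Fixed Female
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the machine-assisted analysis of Drosophila male
    courtship in a reduced paradigm where a wingless female is fixed at
    the center of a circular arena. Provides a synthetic-data generator
    (behavior-structured male trajectories, labeled per-frame feature
    tables, and rendered two-fly grayscale video with ground truth), a
    background-subtraction tracker that recovers body and wing poses, a
    boosted decision-stump behavior classifier with a tapping >
    scissoring > orienting precedence hierarchy and courtship-bout
    masking, and the downstream spatial and temporal statistics: the
    50-bin courtship path, the anterior-to-posterior maximum distance
    ratio (DA/DP), per-behavior angular locations with Rayleigh and
    gated bimodal (axial) Rayleigh tests, courtship latency and indices,
    and sideways-velocity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    rpart,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'circular.R'
    'scenarios.R'
    'generate.R'
    'features-synth.R'
    'render.R'
    'tracking.R'
    'classify.R'
    'spatial.R'
    'temporal.R'
    'io.R'
    'pipeline.R'
    'flycourt-package.R'
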