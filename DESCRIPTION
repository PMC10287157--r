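Package: fingerctx
Title: Task-Context Effects on Intracortical Finger-Movement Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how physical task context (spring resistance,
    altered wrist posture) changes the relationship between motor-cortical
    activity, finger kinematics, and muscle activation in a finger
    brain-machine interface. Provides a synthetic session generator with
    planted low-dimensional latent structure, spiking-band-power and
    threshold-crossing feature extraction, per-channel context-modulated
    tuning regression with false-discovery-rate control, lagged ridge
    decoding with cross-context generalization testing, a position/velocity
    Kalman filter with ReFIT retraining and a closed-loop task simulator,
    online performance and adaptation statistics, neural activity pattern
    readouts, and population-geometry analyses (per-context PCA manifolds,
    principal angles with a resampled control distribution, and demixed PCA
    with marginalization variance fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'session-io.R'
    'generator.R'
    'signal.R'
    'tuning.R'
    'ridge.R'
    'kalman.R'
    'closed-loop.R'
    'patterns.R'
    'geometry.R'
    'dpca.R'
    'fingerctx-package.R'
    'pipeline.R'
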