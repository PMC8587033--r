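Package: footstrike
Title: Automated Foot-Strike Detection from a Pelvis-Worn Smartphone IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects foot-strike events in six-minute walk test recordings
    from a single smartphone inertial sensor worn at the posterior pelvis,
    with emphasis on the variable, asymmetric gait of lower-limb amputees.
    Provides a synthetic gait-signal simulator with known events; zero-phase
    Butterworth low-pass filtering and uniform 50 Hz resampling of
    variably-sampled signals; an automatic peak-pair ground-truth labeller;
    per-frame decision-tree and windowed LSTM classifiers with class
    weighting; post-processing corrections that collapse "banded" consecutive
    predictions onto the anterior-posterior acceleration peak and insert
    missed steps using a per-trial locking period; tolerance-matched event
    evaluation (sensitivity, specificity, accuracy, precision); stride
    parameters (step time, stride time, cadence) compared against minimal
    detectable change; and grouped k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    rpart,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
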