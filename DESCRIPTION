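Package: reachdec
Title: Decoding Reach Kinematics from Electrocorticographic Recordings
Version: 0.1.0
Authors@R:
    person("Reach", "Decoding Maintainers", email = "maintainers@reachdec.org",
           role = c("aut", "cre"))
Description: Toolkit for decoding arm reaching movements from low-channel-count
    electrocorticographic (ECoG) recordings. Provides a seeded synthetic-session
    simulator with known ground truth (minimum-jerk kinematics, per-band
    event-related spectral effects, linear cortico-kinematic encoding), EMG burst
    detection and trial epoching, short-time Fourier ERD/ERS mapping with
    per-subject frequency-band selection, a linear-discriminant movement-onset
    detector scored by F1 and latency, and a gated, lagged multiple linear
    regression decoder of three-dimensional arm velocity with cortico-kinematic
    delay search and leave-one-trial-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
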