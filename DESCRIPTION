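Package: vocotrain
Title: Tone-Vocoder Simulation and Amplitude-Modulation Training Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating auditory training studies on temporal-envelope
    cues and vocoded speech perception. Implements a six-band tone vocoder on an
    ERB_N-number-spaced filterbank (envelope extraction, sine-carrier
    resynthesis), synthesis of amplitude-modulated tone stimuli with
    modulation-power compensation, transformed up-down adaptive staircases for
    three-interval three-alternative forced-choice tasks, maximum-likelihood
    psychometric-function fitting with track quality control and outlier
    screening, Miller-Nicely information-transfer analysis of consonant
    confusion matrices, and an end-to-end study pipeline (group assignment,
    descriptive statistics, mixed-model contrasts) exercised on simulated
    observers with known psychometric functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    lme4,
    lmerTest,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
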