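Package: physync
Title: Inter-Subject Correlation Analysis of Wearable Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying physiological synchrony in wearable
    heart-rate and electrodermal-activity recordings of groups exposed to a
    shared narrative stimulus. Implements sliding-window dyadic inter-subject
    correlations (ISC) and participant-to-group ISC, a circular-shuffle
    permutation test of ISC significance, artifact cleaning and epoching rules
    for wearable sensors, and resampling experiments that characterize how the
    fraction of participants with significant synchrony depends on stimulus
    duration and group size. A synthetic cohort generator with known coupling
    gains, skin-conductance-response-shaped phasic EDA, integer-quantized
    1 Hz heart rate and injectable sensor artifacts makes the whole pipeline
    testable without any recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
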