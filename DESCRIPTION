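Package: physiofuse
Title: Multi-Rate Physiological Sensor Fusion and Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for multi-device physiological monitoring
    pipelines: master-clock synchronization of heterogeneous-rate sensor
    streams with sample-and-hold placeholder semantics, cross-correlation
    clock alignment and gap patching of cached device recordings, ECG R-peak
    detection with instantaneous heart-rate derivation and quality scoring,
    between-device agreement statistics (Pearson, Bland-Altman limits of
    agreement, proportional bias), tissue-oxygenation (StO2) plausibility
    filtering and placement-error rates, and an EEG cognitive pipeline
    (blink-segment ICA cleaning with weight transfer, two-stage epoch
    rejection, spherical-spline channel interpolation, Morlet time-frequency
    maps with divisive dB baselines, Simon-task trial classification). A
    ground-truthed synthetic multi-sensor session generator exercises every
    stage without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
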