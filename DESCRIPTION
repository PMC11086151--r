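Package: eegplotnet
Title: Seizure Classification from Clinical EEG Waveform Plot Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An image-based pipeline for discriminating epileptic seizures (ES)
    from psychogenic non-epileptic seizures (PNES). Multichannel scalp EEG is
    band-pass filtered, re-derived into the four clinical display montages,
    rendered as calibrated waveform plot images, screened by ictal-content and
    EMG pixel-density filters, classified by a small trainable convolutional
    network with the standard transfer-learning recipe, and scored with
    confusion-matrix diagnostics and Wilson score intervals. A seeded synthetic
    EEG generator provides complete cohorts (background rhythms, evolving
    rhythmic ictal discharges, movement/EMG artifact bursts) so the whole
    pipeline runs and is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    png,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
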