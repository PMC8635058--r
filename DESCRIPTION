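Package: erspcluster
Title: Statistics-Guided Classification of EEG Scalp Topograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for cross-subject decoding of visual
    stimulus ambiguity from EEG. Simulates multichannel stimulus-locked
    EEG epochs with class-dependent oscillatory bursts over 1/f
    background noise, computes Morlet-wavelet event-related spectral
    perturbation (ERSP), selects time-frequency features shared across
    subjects with a paired cluster-based permutation test over
    (channel, frequency, time) triplets, renders per-trial scalp
    topograms for the selected clusters, classifies them with a small
    convolutional neural network under leave-one-subject-out
    cross-validation, and quantifies the stability of cluster bounds
    against subject exclusion together with its relation to decoding
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
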