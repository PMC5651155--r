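Package: spikegp
Title: Interictal MEG Spike Detection with Genetic-Programming Features and KNN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient-independent detection of interictal spikes in multichannel
    magnetoencephalography (MEG) recordings. Channels are segmented into
    overlapping 100 ms windows, median-smoothed, and summarised by eight
    statistical features (max, min, mean, standard deviation, median,
    interquartile range, kurtosis, skewness). Genetic programming evolves a
    single scalar formula over these features, scored by the misclassification
    rate of a one-dimensional K-nearest-neighbour classifier on a balanced
    validation group; the evolved formula then drives per-channel KNN decisions
    that are combined by strict regional majority voting. A synthetic
    multichannel spike simulator (band-limited background plus coherent
    biphasic transients) makes the whole pipeline testable without clinical
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
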