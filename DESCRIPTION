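Package: sleepahi
Title: Sleep Apnea Scoring and Apnea-Hypopnea Index Estimation from
    Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Detects sleep-breathing events (apnea and hypopnea) from a
    single-lead electrocardiogram and estimates the apnea-hypopnea index
    (AHI) per recording. Raw ECG is downsampled, bandpass filtered and
    reduced to R-R interval and R-peak amplitude series; recordings are
    segmented on a 10-second grid with strict-enclosure event labels and
    overlapped 1-minute/5-minute context windows; a dual-path
    convolutional feature extractor with channel-attention fusion feeds a
    gated recurrent unit that scores every segment, and consecutive
    positive segments are collapsed into single events to compute the
    AHI. Includes a synthetic annotated apneic-ECG generator so the whole
    pipeline can be trained and validated without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
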