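Package: ppgdtw
Title: Boosted Subsequence Dynamic Time Warping for PPG Beat Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming segmentation of quasi-periodic photoplethysmogram (PPG)
    waveforms into cardiac cycles with simultaneous identification of fiducial
    points (pulse onset/endpoint, maximum-slope point, systolic peak). The
    endpoint decision fuses a domain heuristic (upstroke steepness of candidate
    onsets, with the search window constrained by an FFT-derived average cycle
    length) with a dynamic-time-warping morphology likelihood against an
    annotated single-cycle template, and a dynamic template ensemble built by
    DTW barycenter averaging adapts to evolving waveform morphology. Includes
    the classic SPRING subsequence-matching baseline, beat-level evaluation
    metrics (precision/recall/F1, timestamp RMSE, interbeat-interval agreement)
    and a seeded synthetic PPG generator with exact ground-truth fiducials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
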