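Package: sf6mbw
Title: Analysis of Molar-Mass-Based Infant SF6 Multiple-Breath Washout Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts a sulfur hexafluoride (SF6) concentration signal from raw
    ultrasonic-flowmeter recordings (flow plus speed-of-sound-based molar mass)
    of infant multiple-breath washout tests, and computes the primary outcomes:
    functional residual capacity (FRC), cumulative expired volume (CEV) and
    lung clearance index (LCI). Tidal temperature, humidity and gas-exchange
    confounders are removed by normalising the molar-mass signal against
    volume-domain boundary respirograms recorded at known tracer
    concentrations; the lagging contribution of the flowmeter's side chambers
    is estimated from washout inspirations and removed. A physics-based
    forward simulator of the washin/washout experiment with known ground truth
    is included, so the full analysis chain can be exercised and validated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
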