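Package: mirsvr
Title: MicroRNA Target-Site Prediction and Downregulation Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seed-weighted local alignment for discovering canonical and
    non-canonical microRNA target sites in 3' UTRs, duplex and contextual
    site features (seed match bits, 3' supplementary pairing, AU context,
    partition-function accessibility, conservation), a sigmoid-calibrated
    linear nu support-vector regression of expression downregulation, and
    ranking/ROC/detection-rate evaluation machinery, together with a
    synthetic transfection-experiment generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    minpack.lm,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
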