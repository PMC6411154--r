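Package: limbicnet
Title: Functional-Structural Network Scores and Calcium Event Analysis for
    Drug-Modulated Limbic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks brain regions by drug-induced decoupling of immediate-early-gene
    (c-Fos) activity from the anatomical connectome. Region-wise z-scored group
    activity profiles are correlated across anxiety conditions within each drug
    state; per-region correlation sums (phi) are weighted by out-normalized
    directed connectome edges (phi_con), and drug-minus-saline differences rank
    candidate target regions. Also implements a deep-brain calcium imaging event
    pipeline (deltaF/F0 normalization, zero-phase 2 Hz low-pass filtering,
    thresholded transient detection with decay-time gating, cumulative-amplitude
    event scores, unit classification and cell-type association), and synthetic
    data generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
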