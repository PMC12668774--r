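Package: schicenhance
Title: Single-Cell Hi-C Contact Map Enhancement with a Symmetry-Preserving GAN
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enhances sparse single-cell Hi-C (scHi-C) contact matrices with a
    dual-branch generative adversarial network whose generator extracts rank-one
    (n-by-1 kernel) features, recalibrates channels with squeeze-and-excitation
    attention, and reconstructs exactly symmetric contact maps via outer products
    of learned vectors.  Ships a synthetic scHi-C simulator with planted distance
    decay, A/B compartments, TAD blocks and loops; an evaluation suite (MAE,
    binarized macro F1, stratum-adjusted correlation, random-walk graph
    concordance, flexible bin-shift and loop matching); and downstream callers
    for A/B compartments and insulation-score domain boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
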