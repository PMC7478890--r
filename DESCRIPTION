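Package: isobliss
Title: Isobologram and Bliss Independence Analysis for Drug Combination Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies drug-drug synergy from plate-reader viability data using
    the two classical reference models of additivity. Fits four-parameter
    logistic (variable-slope) dose-response curves, builds dose-equivalent
    (DEQ) mixture designs on a 1/3-log grid anchored at each drug's EC50,
    performs Loewe-additivity isobologram analysis with Combination Indices,
    computes Bliss independence scores (Bliss Index and excess over Bliss)
    over full dose matrices or dose-equivalent bands, and extends the
    Combination Index to three-drug vertical-inhibition designs. Ships a
    plate-data simulator with known ground truth (Loewe-additive,
    Bliss-independent, or synergy-injected response surfaces) so every
    analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
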