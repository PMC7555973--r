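Package: profacc
Title: Personality Judgment Accuracy from Trait and Profile Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores interpersonal-accuracy studies in which judges rate a set
    of target persons on several traits against criterion scores. Computes the
    three standard accuracy indices (trait accuracy, overall profile accuracy,
    distinctive profile accuracy) with Fisher-z aggregation and availability
    rules, their trait, modality and gender-pairing subscores, reliability
    (Cronbach's alpha over trait-by-modality cells and split-half replicability
    of profile correlations), attenuation-corrected correlations with external
    ability measures, and chance-level t tests. Includes a calibrated
    synthetic-data generator emulating a judges x targets x traits Likert
    rating design for validation and power work, and report writers mirroring
    the usual descriptives-and-intercorrelation table layout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
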