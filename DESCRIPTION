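Package: vitalvoice
Title: Voice-Based Vitality and Mental Activity Indices for Depressive
    Mood Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes voice-derived mood indices from per-utterance emotion
    scores: vivacity (joy relative to sorrow), relaxation (calmness relative
    to excitement), their weighted combination vitality, and the longitudinal
    mental-activity index. Includes energy-threshold utterance segmentation
    of PCM WAV recordings, a reader for emotion-score tables with a strict
    0-10 integer contract, a screening evaluation layer (Tukey-Kramer group
    comparison, empirical ROC/AUC, Youden cutpoint, Cohen's d, noncentral-t
    power and sample-size analysis), and a synthetic cohort generator for
    end-to-end testing without patient audio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
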