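Package: negscope
Title: Negation and Speculation Cue and Scope Detection with Super-Tuned
    Sentence Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for biomedical negation and speculation modelling:
    a BioScope-dialect XML and *SEM-2012 CoNLL corpus reader/writer, a
    synthetic corpus and scored sentence-pair generator, a Siamese
    cosine-similarity ("super-tuning") training objective over a small
    trainable sentence encoder, word/subword label alignment with
    padding conventions, token-classification harnesses for cue
    detection (four-class and three-class schemes) and per-cue scope
    resolution with [NEG]/[SPE] marker tokens, and token-level F1 and
    exact-span evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
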