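Package: kdse
Title: Knowledge-Driven Extraction of Drug Side-Effect Pairs from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Large-scale extraction of drug side-effect (drug-SE) pairs from a
    sentence-segmented corpus of biomedical abstracts.  Known drug-SE pairs act
    as prior knowledge to gate sentence- or abstract-level classification
    before noun-phrase-restricted co-occurrence extraction, alongside a
    TF-IDF/SVM sentence-classification baseline, a per-drug
    precision/recall/F1 evaluation protocol, shared-side-effect correlation
    curves against drug attribute and score tables, and a latent-class
    synthetic corpus generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
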