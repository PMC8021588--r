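Package: pcrlingo
Title: Predict PCR Outcomes by Encoding Primer-Template Interactions as
    Pseudo-Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes every primer-pair by template combination as a
    "pseudo-sentence" of five-letter words (pentacodes) derived from
    predicted duplex structures: primer hairpins, primer dimers,
    3'-anchored partial primer-template duplexes, primer binding to the
    fully complementary PCR product, and the thermodynamically selected
    priming sites under a nearest-neighbor Gibbs-energy model. A
    recurrent (LSTM) binary classifier is trained on the resulting
    sentences to predict PCR success, with stratified grouped
    cross-validation, per-template undersampling, confusion-matrix
    metrics, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
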