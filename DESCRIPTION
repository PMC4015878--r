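Package: ratechange
Title: Mining Rate-Change Evidence for Transcriptional Regulation from
    Literature Sentences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects sentences in PubMed/MEDLINE abstracts that describe
    rate changes (speed-ups, delays, or other alterations) in
    transcriptional regulation, a source of qualitative evidence for time
    delays in gene regulatory networks. Implements trigger-word lexicon
    filtering of sentences by cosine similarity, deterministic rule
    classification driven by a transcription rate-change ontology and a
    negative (veto) ontology with typed-relation transitive inference, and
    ontology-guided dependency-path feature extraction for separating
    direct from indirect evidence with a decision-tree learner. Ships a
    synthetic labeled-corpus generator so every pipeline stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
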