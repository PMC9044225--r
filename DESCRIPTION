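Package: negscope
Title: Negation and Uncertainty Cue and Scope Detection in Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for detecting negation and uncertainty (speculation)
    in Spanish clinical text, cast as single-stage BIO sequence labeling
    over cues and their scopes. Reads standoff-annotated corpora (BRAT
    .txt/.ann pairs, including discontinuous spans), computes corpus
    descriptive statistics, encodes sentences into padded token/label
    matrices, and trains two tagger families implemented natively in R: a
    bidirectional LSTM with a linear-chain CRF output layer (exact Viterbi
    decoding, forward-algorithm likelihood) and a small transformer encoder
    with a softmax token-classification head over WordPiece sub-words.
    Includes the full evaluation protocol (token-level partial match,
    entity-level exact match, support-weighted label rollups,
    inter-annotator agreement as F-measure, k-fold cross-validation) and a
    synthetic clinical-corpus generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
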