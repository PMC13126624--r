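Package: atcgen
Title: Multimodal Sequence-to-Sequence Generation of ATC Drug
    Classification Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative prediction of WHO Anatomical Therapeutic Chemical
    (ATC) codes from chemical structure alone.  SMILES strings are mapped to
    four-level ATC codes by character-level encoder-decoder models (a
    bidirectional LSTM and a Transformer), optionally fused with molecular
    descriptor vectors for multimodal learning.  Beam search produces ranked
    candidate codes, and a meta-model chooses how many candidates to accept
    per compound so as to maximise the per-compound F1 score.  The package
    also provides dataset standardisation and filtering utilities, descriptor
    pruning, level-wise hierarchical evaluation metrics, random and
    hierarchical classifier baselines, new-drug and drug-repurposing data
    splits, and a synthetic-grammar fixture generator for testing the whole
    pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    ranger,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
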