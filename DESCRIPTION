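Package: invfold
Title: Fixed-Backbone Protein Sequence Design with a Message-Passing Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based inverse protein folding: designs amino-acid sequences
    for fixed protein backbones using a k-nearest-neighbor residue graph with
    radial-basis-expanded interatomic distance features, a message-passing
    encoder with edge updates, and an order-agnostic autoregressive decoder.
    Supports fixed, tied (symmetric), and multi-state positions during
    sampling, temperature control, teacher-forced scoring (log probability,
    perplexity, sequence recovery), noise-augmented training with
    cluster-aware data splits, and a synthetic-backbone generator with a
    deterministic geometry-to-sequence code for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
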