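Package: biomek
Title: Meta-Knowledge Assignment for Biomedical Events
Version: 0.1.0
Authors@R:
    person("biomek", "developers", email = "biomek@example.org", role = c("aut", "cre"))
Description: Assigns five dimensions of meta-knowledge (Knowledge Type,
    Certainty Level, Polarity, Manner, Source) plus derived hyper-dimensions
    to biomedical events annotated in BioNLP-ST-style standoff format with
    token-aligned dependency parses.  Provides standoff and CoNLL-style
    parse readers/writers, pointwise-mutual-information induction of cue
    (clue) word lexicons, dependency shortest-path and n-gram feature
    extraction with feature hashing and type-based L2 normalisation,
    one-vs-rest linear squared-hinge classifiers with class-biased
    regularisation, annotation transfer between corpora, score stacking
    from an auxiliary model, per-value/macro/micro evaluation with a
    majority baseline, and a seeded synthetic-corpus generator so the full
    pipeline can be exercised without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
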