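Package: ClinCooccur
Title: Temporal Co-Occurrence Matrices from Clinical Note Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds term and concept co-occurrence matrices from corpora of
    timestamped clinical notes. Notes are annotated against a user-supplied
    lexicon with stop-word, short-term and name-homonym suppression and
    NegEx-style negation and section flagging, hashed into per-patient
    temporal bins via a randomized-offset floor formula, and counted under
    per-bin and per-patient aggregation. Singleton and pairwise co-frequency
    counts are serialized as tab-delimited data records with ID dictionaries
    and decode utilities, and feed association statistics (contingency
    tables, odds ratio, relative risk, chi-squared, G-test, Bayesian
    conditionals, lift), correlated-feature grouping, and co-occurrence
    adjusted enrichment analysis. A synthetic-corpus simulator with planted
    associations provides ground-truth counts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
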