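Package: costylo
Title: Co-Authorship Stylometry for Facilitated-Communication Dialogue Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting user and facilitator stylistic
    contributions in facilitated-communication (FC) dialogue transcripts.
    Parses caps-lock dialogue session files, assembles per user-facilitator
    pair texts, extracts most-frequent-word and character n-gram profiles,
    computes cosine-delta and Burrows-delta distance tables, builds cluster
    dendrograms and scores same-user leaf pairing, performs the facilitator
    "red line" rank analysis with permutation nulls, classifies text-pair
    relationships into five groups with the associated statistics, and
    aggregates bootstrap consensus networks over feature-size sweeps. A
    synthetic corpus generator with a known user/facilitator unigram mixture
    model provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
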