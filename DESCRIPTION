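Package: dosagenet
Title: Gene Dosage Networks for CNV-Based Differential Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds participant-gene-GO networks from copy-number-variation
    (CNV) cohorts in which each participant carries duplications (+1) or
    deletions (-1) over a curated gene set, characterises their topology
    (centrality summaries, degree distributions contrasted with Poisson and
    power-law reference curves, hub and neighbourhood analysis), projects
    per-diagnosis gene-gene and GO-GO similarity networks with community
    detection, and converts network topology into signed importance feature
    vectors for repeated balanced Random-Forest differential diagnosis
    (e.g. autism spectrum disorder versus developmental delay). Includes a
    synthetic cohort generator with planted hub and block structure so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    pROC,
    pracma,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
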