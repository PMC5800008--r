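Package: methylShapeR
Title: Pentamer-Based Prediction of CpG Methylation Effects on DNA Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-throughput prediction of the effect of CpG methylation on
    local DNA shape features (minor groove width, propeller twist, roll and
    helix twist). Sequences are modelled over a six-letter alphabet in which
    "m" denotes 5-methylcytosine and "g" the guanine paired with it on the
    opposite strand. Pentamer query tables are mined from pools of
    per-fragment shape records by a sliding-window approach, queried in a
    strand-independent manner, and used to profile shape features of
    arbitrary sequences and to compute methylation-induced shape changes
    (delta-shape). Downstream, delta-shape feeds linear shape-to-affinity
    models of DNase I cleavage (elastic-net regression on hexamer features)
    and a comparator for methylation effects on Pbx-Hox binding sites,
    including context-matched minor-groove-width estimates via CpG-context
    k-mer tables. A seeded synthetic-data generator with planted ground
    truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
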