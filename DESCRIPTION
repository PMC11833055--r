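Package: fcconcord
Title: Cross-Study Transcriptome Fold-Change Concordance and Behavioral Index Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to compare ground-based microgravity models (3D clinostat,
    hindlimb unloading) against spaceflight transcriptomes via an L1 distance on
    shared-gene log2 fold-change profiles, with differential-expression
    thresholding, three-way DEG overlap partitioning and heatmap gene selection.
    Includes a negative-binomial multi-study count simulator with a planted
    concordance parameter, a lightweight two-group differential-expression
    engine (Welch t on log2 CPM), and rodent behavioral index formulas
    (novel-object recognition index, Y-maze spontaneous alternation, elevated
    plus maze open-arm percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
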