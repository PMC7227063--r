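Package: gsgtools
Title: Genome Segment Graphs and Multiple Compatible Arrangements for
    Transcriptomic Structural Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data structures and solvers for detecting transcriptomic
    structural variants (TSVs) from genome segment graphs (GSGs) in
    heterogeneous samples. Provides the Multiple Compatible Arrangements
    Problem (MCAP) objective, greedy approximation solvers with provable
    floors, an exact integer-linear-programming formulation for k
    arrangements solved by a built-in branch-and-bound backend, per-edge
    conflict-structure classification that quantifies sample heterogeneity,
    a TSV caller with BEDPE output, a brute-force oracle for small
    instances, and a seeded synthetic instance generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
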