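Package: scsbeam
Title: Probabilistic Beam Search Heuristics for the Shortest Common
    Supersequence Problem
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solvers for the shortest common supersequence problem (SCSP):
    classical constructive heuristics (Majority Merge, Weighted Majority
    Merge, Alphabet Leftmost), a probabilistic beam search with an
    embedding-probability heuristic and dominance pruning, beam-search
    based reduction and perturbation local searches, and an anytime
    multilevel driver that alternates them under a wall-clock budget.
    Includes an exact dynamic-programming solver for small instances,
    seeded random instance generation for benchmarking, plain-text and
    FASTA instance input, and trace/result export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
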