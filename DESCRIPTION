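Package: splitmatch
Title: Split-Based Exact Pattern Matching with Comparison-Count Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact string matching by pattern splitting: the query is divided
    into two halves, the right half is searched anchor-first with unit shifts
    and no precomputed shift tables, and the left half is verified through a
    constant-time position mapping. Ships instrumented reference
    implementations of the classical comparators (brute force, Boyer-Moore,
    Horspool, Quick Search), readers for plain-text corpora, FASTA files and
    pattern lists, seeded generators for synthetic corpora with
    planted-pattern ground truth, and a benchmark harness that reports
    portable metrics (character comparisons, alignments, auxiliary-space
    proxy) instead of hardware-bound wall-clock times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    stringi,
    optparse
Config/testthat/edition: 3
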