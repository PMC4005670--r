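Package: strainmark
Title: Genome-Specific 50-mer Markers for Strain-Level Metagenome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects genome-specific 50-base markers (GSMs) from collections
    of closely related microbial genomes by shared k-mer stretch filtering
    (18-20-mers occurring in two or more taxa, plus all host k-mers) and a
    global-identity filter (maximum 85 percent identity against non-target
    genomes), with a progressive k schedule and a minimum of 50 markers per
    target. Identifies strains and species in shotgun metagenomes by exact
    full-length marker matching, calls targets positive at a 10 percent
    panel threshold, and normalises hit counts to per-platform scales.
    Includes group-comparison statistics (pooled t-test, Benjamini-Hochberg
    FDR with an abundance gate, log response ratios with delta-method
    confidence intervals) and a synthetic community generator: strain
    families with controlled divergence and error-free paired-end read
    simulation at specified fold-coverage for sensitivity and mock-community
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
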