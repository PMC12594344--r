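Package: hfrmap
Title: Recombination Tract Detection and Selected-Locus Mapping for
    Bacterial Conjugation Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bacterial conjugation crosses between a
    donor and a recipient strain. Detects donor-derived recombination
    tracts in sequenced recombinant clones by two independent methods (a
    two-state hidden Markov model on competitively mapped read labels,
    and penalized changepoint segmentation of donor-allele frequencies at
    core-genome polymorphic sites), localizes a selected locus from
    pooled recombinant sequencing via binned donor/recipient coverage
    log-ratios, and implements the interval-intersection model relating
    mapping precision to the harmonic mean of recombined fragment
    lengths. A synthetic-cross generator (genome pairs, recombinant
    clones, reads, pools, with machine-readable truth) drives all
    analyses so no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
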