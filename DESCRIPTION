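Package: ribostall
Title: Ribosome Traffic Simulation and Detection of Rate-Limiting Elongation Stalls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to decide whether reduced ribosome-footprint coverage on a
    transcript reflects rate-limiting translation elongation (a ribosome
    traffic jam behind a pause site) or reduced translation initiation. The
    package provides a continuous-time Gillespie implementation of the
    inhomogeneous l-TASEP (totally asymmetric simple exclusion process with
    extended particles) to simulate ribosome traffic in known regimes, a
    Kolmogorov-Smirnov stall score computed between smoothed, normalized
    per-codon footprint densities of paired control/mutant ribosome profiling
    samples, target-set enrichment of stall-score groups, and supporting
    expression, transcript-length, binding-motif, and gene-dosage summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
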