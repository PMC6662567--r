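Package: metabin
Title: Adaptive Metagenome Binning from Tetranucleotide Composition and
    Multi-Sample Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups assembled metagenome contigs into putative genome bins
    using a composite similarity score that combines tetranucleotide
    frequency (TNF) composition, per-sample read-depth agreement (ABD) and
    depth correlation across samples (COR), with quantile normalization to
    place all evidence on a common scale.  Clustering proceeds on a sparse
    capped-degree similarity graph partitioned by a deterministic,
    edge-strength-ordered label propagation algorithm whose membership calls
    combine edge evidence with Fisher's method.  Small contigs (1-2.5 kb)
    and members of dissolved small bins are recruited afterwards by coverage
    correlation when three or more samples are available.  Includes a
    synthetic multi-sample community simulator with ground truth, a
    completeness/precision evaluator, and a genetic-algorithm parameter
    search.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
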