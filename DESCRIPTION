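Package: HiCdomains
Title: Integrative Chromatin Domain Annotation from Hi-C Embeddings and 1D Genomic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls combinatorial chromatin domain types by combining genome-wide
    structural features, learned from an observed/expected Hi-C interaction graph
    with a second-order-proximity node embedding trained by edge sampling and
    negative sampling, with binned 1D functional genomic signals in a
    Gaussian-emission hidden Markov model. Includes the evaluation statistics for
    domain annotations (variance explained for arbitrary signals, gene expression
    and multi-phase replication timing; ChIA-PET loop observed/expected enrichment;
    fold-change overlap and adjusted Rand index; block/resampling bootstrap
    standard errors) and a fully synthetic data generator with planted functional
    and structural domain states for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
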