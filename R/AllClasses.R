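#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors Pairs
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Pairs first second queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom stats kmeans sd quantile rnorm rpois runif rlnorm dnorm var median
#' @importFrom utils read.table write.table head tail
#' @importFrom data.table data.table fread fwrite setorder as.data.table :=
#' @importFrom Rcpp evalCpp
#' @useDynLib HiCdomains, .registration = TRUE
NULL

.datatable.aware <- TRUE

#' BinnedGenome: a fixed-resolution binning of named chromosomes
#'
#' The shared coordinate system for the whole pipeline: every chromosome is
#' tiled with contiguous, non-overlapping bins of width \code{resolution}
#' (0-based half-open internally; the last bin of a chromosome may be short).
#' Bins carry global indices \code{1..nbins(x)} in chromosome declaration
#' order.
#'
#' @slot bins a \link[GenomicRanges]{GRanges} of the bins, in global-index order
#' @slot resolution bin width in bp
#' @slot chromLengths named numeric of chromosome lengths in declaration order
#' @export
setClass("BinnedGenome", representation(
    bins = "GRanges",
    resolution = "integer",
    chromLengths = "numeric"
))

setValidity("BinnedGenome", function(object) {
    msgs <- character()
    if (length(object@resolution) != 1L || object@resolution <= 0L)
        msgs <- c(msgs, "resolution must be a single positive integer")
    if (is.null(names(object@chromLengths)) || anyDuplicated(names(object@chromLengths)))
        msgs <- c(msgs, "chromosome names must be unique and non-empty")
    if (any(object@chromLengths <= 0))
        msgs <- c(msgs, "chromosome lengths must be positive")
    if (length(msgs)) msgs else TRUE
})

#' RawContacts: symmetric binned Hi-C contact counts
#'
#' Sparse symmetric storage of binned contact counts: each unordered bin pair
#' is stored once with \code{i <= j} (global 1-based bin indices); duplicate
#' pairs are summed on construction.
#'
#' @slot entries data.frame with columns \code{i}, \code{j}, \code{count}
#' @slot nbins number of bins in the underlying BinnedGenome
#' @export
setClass("RawContacts", representation(
    entries = "data.frame",
    nbins = "integer"
))

setValidity("RawContacts", function(object) {
    e <- object@entries
    msgs <- character()
    if (!all(c("i", "j", "count") %in% names(e)))
        msgs <- c(msgs, "entries must have columns i, j, count")
    else {
        if (nrow(e) && any(e$i > e$j)) msgs <- c(msgs, "entries must satisfy i <= j")
        if (nrow(e) && any(e$count < 0)) msgs <- c(msgs, "counts must be non-negative")
        if (nrow(e) && (any(e$i < 1) || any(e$j > object@nbins)))
            msgs <- c(msgs, "bin indices out of range")
        if (anyDuplicated(e[c("i", "j")])) msgs <- c(msgs, "duplicate (i, j) pairs")
    }
    if (length(msgs)) msgs else TRUE
})

#' ContactGraph: weighted undirected O/E interaction graph over bins
#'
#' Nodes are the global indices of bins that passed filtering; edges carry
#' positive observed/expected contact enrichment weights. No self-loops.
#'
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{w}
#'   (global bin indices, \code{i < j}, \code{w > 0})
#' @slot nodes integer vector of global bin indices in the graph
#' @slot nbins number of bins in the underlying BinnedGenome
#' @export
setClass("ContactGraph", representation(
    edges = "data.frame",
    nodes = "integer",
    nbins = "integer"
))

setValidity("ContactGraph", function(object) {
    e <- object@edges
    msgs <- character()
    if (!all(c("i", "j", "w") %in% names(e)))
        msgs <- c(msgs, "edges must have columns i, j, w")
    else if (nrow(e)) {
        if (any(e$i >= e$j)) msgs <- c(msgs, "edges must satisfy i < j (no self-loops)")
        if (any(e$w <= 0)) msgs <- c(msgs, "edge weights must be positive")
        if (!all(c(e$i, e$j) %in% object@nodes))
            msgs <- c(msgs, "edge endpoints must be graph nodes")
    }
    if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: bins-by-tracks real-valued feature matrix
#'
#' Holds either binned 1D functional signals or learned structural embedding
#' features, aligned to a \linkS4class{BinnedGenome}. \code{mask} marks usable
#' bins; masked-out rows are excluded from all downstream statistics.
#'
#' @slot values numeric matrix (rows = bins, columns = tracks; colnames are
#'   track names)
#' @slot noData logical matrix, same shape: TRUE where a track had no data
#'   over the bin (value stored as 0)
#' @slot mask logical per bin; TRUE = usable
#' @slot preproc list recording any preprocessing applied (transform name and
#'   per-track centering/scaling constants), empty if raw
#' @export
setClass("FeatureMatrix", representation(
    values = "matrix",
    noData = "matrix",
    mask = "logical",
    preproc = "list"
))

setValidity("FeatureMatrix", function(object) {
    msgs <- character()
    if (!identical(dim(object@values), dim(object@noData)))
        msgs <- c(msgs, "values and noData must have identical dimensions")
    if (length(object@mask) != nrow(object@values))
        msgs <- c(msgs, "mask length must equal the number of bins")
    if (is.null(colnames(object@values)))
        msgs <- c(msgs, "values must have track names as colnames")
    if (length(msgs)) msgs else TRUE
})

#' DomainAnnotation: one domain label per genomic bin
#'
#' Per-bin integer labels in \code{1..K}, with \code{NA} where the feature
#' mask excluded the bin. Coverage is the fraction of annotated bins carrying
#' each label and sums to one.
#'
#' @slot labels integer vector, one per bin, NA allowed
#' @slot K number of domain types
#' @slot meta list of provenance (mode, seed, fitted model, ...)
#' @export
setClass("DomainAnnotation", representation(
    labels = "integer",
    K = "integer",
    meta = "list"
))

setValidity("DomainAnnotation", function(object) {
    msgs <- character()
    lab <- object@labels[!is.na(object@labels)]
    if (length(lab) && (any(lab < 1L) | any(lab > object@K)))
        msgs <- c(msgs, "labels must lie in 1..K")
    if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' EmbeddingModel: node embeddings of the contact graph
#'
#' Stores the per-node embedding vectors \code{u} and context vectors
#' \code{uCtx} learned from the second-order-proximity objective. Only
#' \code{u} is exported as structural features.
#'
#' @slot dim embedding dimension
#' @slot u numeric matrix, |V| x dim: the node embeddings
#' @slot uCtx numeric matrix, |V| x dim: the context vectors
#' @slot nodes global bin indices of the embedded nodes (graph nodes with at
#'   least one edge)
#' @slot trained logical
#' @slot seed integer RNG seed used for training
#' @export
setClass("EmbeddingModel", representation(
    dim = "integer",
    u = "matrix",
    uCtx = "matrix",
    nodes = "integer",
    trained = "logical",
    seed = "integer"
))

setValidity("EmbeddingModel", function(object) {
    msgs <- character()
    if (!identical(dim(object@u), dim(object@uCtx)))
        msgs <- c(msgs, "u and uCtx must have identical shape")
    if (nrow(object@u) != length(object@nodes))
        msgs <- c(msgs, "one embedding row per node required")
    if (ncol(object@u) != object@dim)
        msgs <- c(msgs, "embedding width must equal dim")
    if (length(msgs)) msgs else TRUE
})

#' HmmModel: Gaussian-emission hidden Markov model (or GMM) over feature bins
#'
#' Emissions are per-state diagonal-covariance Gaussian mixtures (M components
#' per state, default 1). A plain Gaussian mixture model is represented as the
#' degenerate case with no chain dependency (\code{type = "gmm"}).
#'
#' @slot K number of hidden states
#' @slot M mixture components per state
#' @slot type "hmm" or "gmm"
#' @slot initProb initial state distribution, length K
#' @slot transMat K x K transition matrix (rows sum to 1); identity-like and
#'   unused for type "gmm"
#' @slot mixWeights K x M mixture weights (rows sum to 1)
#' @slot means array K x M x D of component means
#' @slot vars array K x M x D of component variances (diagonal covariances)
#' @slot preproc the preprocessing record of the features the model was fit on
#' @slot logLik final training log-likelihood
#' @slot seed integer seed used for initialization
#' @export
setClass("HmmModel", representation(
    K = "integer",
    M = "integer",
    type = "character",
    initProb = "numeric",
    transMat = "matrix",
    mixWeights = "matrix",
    means = "array",
    vars = "array",
    preproc = "list",
    logLik = "numeric",
    seed = "integer"
))

setValidity("HmmModel", function(object) {
    msgs <- character()
    if (!object@type %in% c("hmm", "gmm")) msgs <- c(msgs, "type must be 'hmm' or 'gmm'")
    if (abs(sum(object@initProb) - 1) > 1e-8) msgs <- c(msgs, "initProb must sum to 1")
    if (any(abs(rowSums(object@transMat) - 1) > 1e-8))
        msgs <- c(msgs, "transition rows must sum to 1")
    if (any(object@vars <= 0)) msgs <- c(msgs, "variances must be positive")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: planted domain states for a synthetic genome
#'
#' The ground truth behind a synthetic dataset: per-bin combined states and
#' their functional and structural factor projections, plus the generator
#' configuration.
#'
#' @slot genome the BinnedGenome
#' @slot combined per-bin combined state in 1..(F*S)
#' @slot functional per-bin functional factor in 1..F
#' @slot structural per-bin structural factor in 1..S
#' @slot config list of all generator parameters including the seed
#' @export
setClass("SyntheticTruth", representation(
    genome = "BinnedGenome",
    combined = "integer",
    functional = "integer",
    structural = "integer",
    config = "list"
))

setValidity("SyntheticTruth", function(object) {
    msgs <- character()
    n <- length(object@genome@bins)
    if (length(object@combined) != n || length(object@functional) != n ||
        length(object@structural) != n)
        msgs <- c(msgs, "state vectors must have one entry per bin")
    if (length(msgs)) msgs else TRUE
})
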