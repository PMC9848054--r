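#' @name accessors
#' @title Accessors for HiCdomains classes
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
#' @param x an object
#' @param ... unused
NULL

#' @rdname accessors
#' @export
setGeneric("nbins", function(x, ...) standardGeneric("nbins"))

#' @rdname accessors
#' @export
setGeneric("binRanges", function(x, ...) standardGeneric("binRanges"))

#' @rdname accessors
#' @export
setGeneric("binResolution", function(x, ...) standardGeneric("binResolution"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x, ...) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("contactEntries", function(x, ...) standardGeneric("contactEntries"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x, ...) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x, ...) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("nodeDegrees", function(x, ...) standardGeneric("nodeDegrees"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("trackNames", function(x, ...) standardGeneric("trackNames"))

#' @rdname accessors
#' @export
setGeneric("binMask", function(x, ...) standardGeneric("binMask"))

#' @rdname accessors
#' @export
setGeneric("domainLabels", function(x, ...) standardGeneric("domainLabels"))

#' @rdname accessors
#' @export
setGeneric("nLabels", function(x, ...) standardGeneric("nLabels"))

#' @rdname accessors
#' @export
setGeneric("labelCoverage", function(x, ...) standardGeneric("labelCoverage"))

#' @rdname accessors
#' @export
setGeneric("embeddings", function(x, ...) standardGeneric("embeddings"))

#' @rdname accessors
#' @export
setMethod("nbins", "BinnedGenome", function(x, ...) length(x@bins))

#' @rdname accessors
#' @export
setMethod("binRanges", "BinnedGenome", function(x, ...) x@bins)

#' @rdname accessors
#' @export
setMethod("binResolution", "BinnedGenome", function(x, ...) x@resolution)

#' @rdname accessors
#' @export
setMethod("chromLengths", "BinnedGenome", function(x, ...) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("contactEntries", "RawContacts", function(x, ...) x@entries)

#' @rdname accessors
#' @export
setMethod("graphEdges", "ContactGraph", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setMethod("graphNodes", "ContactGraph", function(x, ...) x@nodes)

#' Degrees of graph nodes
#'
#' Degree of node i is the sum of the weights of its incident edges; exactly
#' the row sum of the stored symmetric weight matrix.
#'
#' @param x a ContactGraph
#' @param ... unused
#' @return named numeric vector over \code{graphNodes(x)}
#' @export
setMethod("nodeDegrees", "ContactGraph", function(x, ...) {
    d <- numeric(x@nbins)
    e <- x@edges
    if (nrow(e)) {
        a <- tapply(e$w, e$i, sum)
        b <- tapply(e$w, e$j, sum)
        d[as.integer(names(a))] <- d[as.integer(names(a))] + as.numeric(a)
        d[as.integer(names(b))] <- d[as.integer(names(b))] + as.numeric(b)
    }
    out <- d[x@nodes]
    names(out) <- x@nodes
    out
})

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("trackNames", "FeatureMatrix", function(x, ...) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("binMask", "FeatureMatrix", function(x, ...) x@mask)

#' @rdname accessors
#' @export
setMethod("domainLabels", "DomainAnnotation", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("nLabels", "DomainAnnotation", function(x, ...) x@K)

#' Per-label coverage of an annotation
#'
#' Fraction of annotated (non-NA) bins carrying each label; sums to one.
#'
#' @param x a DomainAnnotation
#' @param ... unused
#' @return numeric vector of length \code{nLabels(x)}
#' @export
setMethod("labelCoverage", "DomainAnnotation", function(x, ...) {
    lab <- x@labels[!is.na(x@labels)]
    if (!length(lab)) stop("annotation has no annotated bins")
    tabulate(lab, nbins = x@K) / length(lab)
})

#' @rdname accessors
#' @export
setMethod("embeddings", "EmbeddingModel", function(x, ...) x@u)

setMethod("show", "BinnedGenome", function(object) {
    cat("BinnedGenome:", length(object@chromLengths), "chromosome(s),",
        length(object@bins), "bins at", object@resolution, "bp\n")
})

setMethod("show", "RawContacts", function(object) {
    cat("RawContacts:", nrow(object@entries), "non-zero bin pairs over",
        object@nbins, "bins; total count", sum(object@entries$count), "\n")
})

setMethod("show", "ContactGraph", function(object) {
    cat("ContactGraph:", length(object@nodes), "nodes,", nrow(object@edges),
        "edges (O/E weighted) over", object@nbins, "bins\n")
})

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix:", nrow(object@values), "bins x", ncol(object@values),
        "tracks;", sum(object@mask), "usable bins",
        if (length(object@preproc)) paste0("; preprocessed (", object@preproc$transform, ")") else "",
        "\n", sep = " ")
})

setMethod("show", "DomainAnnotation", function(object) {
    ann <- sum(!is.na(object@labels))
    cat("DomainAnnotation:", object@K, "domain types over", length(object@labels),
        "bins (", ann, "annotated )\n")
    if (ann) {
        cov <- round(labelCoverage(object), 3)
        cat("  coverage:", paste(sprintf("%d:%.3f", seq_along(cov), cov), collapse = " "), "\n")
    }
})

setMethod("show", "EmbeddingModel", function(object) {
    cat("EmbeddingModel: dim", object@dim, ",", nrow(object@u), "nodes,",
        if (object@trained) "trained" else "untrained", "( seed", object@seed, ")\n")
})

setMethod("show", "HmmModel", function(object) {
    cat(toupper(object@type), "model: K =", object@K, ", M =", object@M,
        ", D =", dim(object@means)[3], ", logLik =", object@logLik, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", max(object@functional), "functional x",
        max(object@structural), "structural =", max(object@combined),
        "combined states over", length(object@combined), "bins\n")
})
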