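#' Training configuration for the structural embedding
#'
#' @param dim embedding dimension (default 8: enough to capture genome-wide
#'   compartmental structure at 100 kb)
#' @param negatives noise (negative) samples per positive edge draw
#' @param samples total number of edge samples; NULL = max(100 x |E|, 1e6)
#' @param rho0 initial learning rate, decayed linearly to rho0 x 1e-4
#' @param noiseExponent exponent of the degree-proportional noise distribution
#' @param seed RNG seed (training is bit-reproducible given the seed)
#' @return a list of class used by \code{\link{trainEmbedding}}
#' @export
trainConfig <- function(dim = 8L, negatives = 5L, samples = NULL,
                        rho0 = 0.025, noiseExponent = 0.75, seed = 1L) {
    stopifnot(dim > 0, negatives > 0, rho0 > 0, is.null(samples) || samples > 0)
    list(dim = as.integer(dim), negatives = as.integer(negatives),
         samples = samples, rho0 = rho0, noiseExponent = noiseExponent,
         seed = as.integer(seed))
}

#' Learn per-bin structural features from the contact graph
#'
#' Optimizes the second-order-proximity objective by stochastic edge sampling
#' with negative sampling: edges are drawn with probability proportional to
#' their weight (each undirected edge feeds both directions), the positive
#' pair ascends \code{sigma(uCtx_j . u_i)}, and \code{negatives} noise nodes
#' drawn proportional to degree^noiseExponent descend it. Node weights equal
#' to degree are honored implicitly by weight-proportional edge sampling.
#' Isolated graph nodes are dropped with a warning before training.
#'
#' @param graph a \linkS4class{ContactGraph}
#' @param config a \code{\link{trainConfig}} list
#' @return a trained \linkS4class{EmbeddingModel}
#' @export
trainEmbedding <- function(graph, config = trainConfig()) {
    e <- graph@edges
    if (!nrow(e)) stop("cannot train on an empty graph")
    connected <- sort(unique(c(e$i, e$j)))
    isolated <- setdiff(graph@nodes, connected)
    if (length(isolated))
        warning(length(isolated), " isolated node(s) dropped before training")
    V <- length(connected)
    samples <- config$samples
    if (is.null(samples)) samples <- max(100 * nrow(e), 1e6)
    src <- match(e$i, connected) - 1L
    dst <- match(e$j, connected) - 1L
    fit <- .lineTrainCpp(src, dst, e$w, V, config$dim, config$negatives,
                         as.numeric(samples), config$rho0,
                         config$noiseExponent, as.numeric(config$seed))
    new("EmbeddingModel", dim = config$dim, u = fit$u, uCtx = fit$ctx,
        nodes = as.integer(connected), trained = TRUE, seed = config$seed)
}

#' Initialize an untrained embedding model for a graph
#'
#' Deterministic initialization matching the trainer: \code{u} uniform in
#' (-0.5/dim, 0.5/dim), context vectors zero. Useful for objective/gradient
#' diagnostics at the starting point.
#'
#' @param graph a \linkS4class{ContactGraph}
#' @param dim embedding dimension
#' @param seed seed for the uniform initialization (R RNG)
#' @param zeroU if TRUE, \code{u} is all zeros too (the analytic limit cases)
#' @return an \linkS4class{EmbeddingModel} with \code{trained = FALSE}
#' @export
initEmbedding <- function(graph, dim = 8L, seed = 1L, zeroU = FALSE) {
    e <- graph@edges
    connected <- sort(unique(c(e$i, e$j)))
    V <- length(connected)
    if (zeroU) {
        u <- matrix(0, V, dim)
    } else {
        set.seed(seed)
        u <- matrix(runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)
    }
    new("EmbeddingModel", dim = as.integer(dim), u = u,
        uCtx = matrix(0, V, dim), nodes = as.integer(connected),
        trained = FALSE, seed = as.integer(seed))
}

## map global bin indices to model rows
.modelRow <- function(model, nodes) match(nodes, model@nodes)

#' Model distribution over contexts for one node
#'
#' The full softmax \code{p(j | i) = exp(uCtx_j . u_i) / sum_k exp(uCtx_k .
#' u_i)} over all embedded nodes. Diagnostic/oracle use only; training never
#' materializes it.
#'
#' @param model an \linkS4class{EmbeddingModel}
#' @param i model row index of the conditioning node (1..nrow of u)
#' @return probability vector over all embedded nodes (sums to 1)
#' @export
secondOrderSoftmax <- function(model, i) {
    logits <- as.numeric(model@uCtx %*% model@u[i, ])
    logits <- logits - max(logits)
    p <- exp(logits)
    p / sum(p)
}

#' Empirical neighbor distribution of a graph node
#'
#' \code{w_ij / d_i} over all embedded/graph nodes; support is the neighbor
#' set of \code{i}. Isolated nodes are an error (they must be dropped before
#' training).
#'
#' @param graph a \linkS4class{ContactGraph}
#' @param i global bin index of the node
#' @return named probability vector over the graph's connected nodes
#' @export
empiricalDistribution <- function(graph, i) {
    e <- graph@edges
    connected <- sort(unique(c(e$i, e$j)))
    p <- stats::setNames(numeric(length(connected)), connected)
    nb <- e[e$i == i | e$j == i, , drop = FALSE]
    if (!nrow(nb)) stop("node ", i, " is isolated; drop isolated nodes before training")
    other <- ifelse(nb$i == i, nb$j, nb$i)
    p[as.character(other)] <- nb$w
    p / sum(p)
}

#' Exact second-order objective
#'
#' \code{O2 = -sum over directed edges of w_ij log p(j | i)} with each
#' undirected edge contributing both directions, using the full softmax.
#' Oracle use on small graphs.
#'
#' @param model an \linkS4class{EmbeddingModel}
#' @param graph the \linkS4class{ContactGraph} it embeds
#' @return a single non-negative real
#' @export
exactObjective <- function(model, graph) {
    e <- graph@edges
    ri <- .modelRow(model, e$i); rj <- .modelRow(model, e$j)
    logits <- model@uCtx %*% t(model@u)   # [context k, node i]
    lse <- apply(logits, 2, function(col) { m <- max(col); m + log(sum(exp(col - m))) })
    logp <- function(tgt, srcn) logits[cbind(tgt, srcn)] - lse[srcn]
    -sum(e$w * (logp(rj, ri) + logp(ri, rj)))
}

#' Analytic gradient of the exact second-order objective
#'
#' Full-softmax (negative-sampling-free) gradient with respect to both the
#' node embeddings and the context vectors; oracle for finite-difference
#' checks on small graphs.
#'
#' @param model an \linkS4class{EmbeddingModel}
#' @param graph the \linkS4class{ContactGraph}
#' @return list with matrices \code{du} and \code{dctx} shaped like
#'   \code{model@u}
#' @export
exactGradient <- function(model, graph) {
    U <- model@u; C <- model@uCtx
    V <- nrow(U); D <- ncol(U)
    e <- graph@edges
    ri <- .modelRow(model, e$i); rj <- .modelRow(model, e$j)
    logits <- C %*% t(U)                    # [k, i]
    P <- apply(logits, 2, function(col) { x <- exp(col - max(col)); x / sum(x) })
    ## directed edge list (both ways)
    srcn <- c(ri, rj); tgt <- c(rj, ri); w <- c(e$w, e$w)
    dU <- matrix(0, V, D); dC <- matrix(0, V, D)
    dOut <- rowsum(w, srcn)                 # total outgoing weight per source
    srcIds <- as.integer(rownames(dOut))
    ## dO2/du_i = -sum_j w_ij (c_j - E_{p(.|i)} c) = -(sum_j w_ij c_j) + d_i E c
    wc <- rowsum(w * C[tgt, , drop = FALSE], srcn)
    expC <- t(t(C) %*% P[, srcIds, drop = FALSE])   # E_{p(.|i)} c per source
    dU[srcIds, ] <- -wc + as.numeric(dOut) * expC
    ## dO2/dc_m = -sum_i (w_im - d_i p(m|i)) u_i
    wTgt <- rowsum(w * U[srcn, , drop = FALSE], tgt)
    tgtIds <- as.integer(rownames(wTgt))
    dC[tgtIds, ] <- dC[tgtIds, ] - wTgt
    ## + sum_i d_i p(m|i) u_i over sources i with outgoing weight
    dC <- dC + P[, srcIds, drop = FALSE] %*% (as.numeric(dOut) * U[srcIds, , drop = FALSE])
    list(du = dU, dctx = dC)
}

#' First-order-proximity objective (diagnostic)
#'
#' \code{-sum over edges of w_ij log sigma(u_j . u_i)}: provided so first-
#' versus second-order embeddings can be compared on synthetic graphs.
#'
#' @param model an \linkS4class{EmbeddingModel}
#' @param graph the \linkS4class{ContactGraph}
#' @return a single real
#' @export
firstOrderObjective <- function(model, graph) {
    e <- graph@edges
    ri <- .modelRow(model, e$i); rj <- .modelRow(model, e$j)
    dots <- rowSums(model@u[ri, , drop = FALSE] * model@u[rj, , drop = FALSE])
    -sum(e$w * log(stats::plogis(dots)))
}

#' Export learned embeddings as structural features
#'
#' Places each embedded node's \code{u} vector at its global bin index; bins
#' without an embedding (masked, or isolated in the graph) get no-data rows
#' and are masked out. Track names are \code{struct_1..struct_dim}.
#'
#' @param model a trained \linkS4class{EmbeddingModel}
#' @param genome the \linkS4class{BinnedGenome}
#' @return a \linkS4class{FeatureMatrix}
#' @export
exportFeatures <- function(model, genome) {
    if (!model@trained) stop("model is not trained")
    n <- nbins(genome)
    vals <- matrix(0, n, model@dim,
                   dimnames = list(NULL, paste0("struct_", seq_len(model@dim))))
    nd <- matrix(TRUE, n, model@dim, dimnames = dimnames(vals))
    vals[model@nodes, ] <- model@u
    nd[model@nodes, ] <- FALSE
    mask <- !nd[, 1]
    new("FeatureMatrix", values = vals, noData = nd, mask = mask, preproc = list())
}
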