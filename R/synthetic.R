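#' Plant combined domain states on a genome
#'
#' Per chromosome, an independent first-order Markov chain over the
#' \code{nFunctional * nStructural} combined states with self-transition
#' probability \code{stickiness} and the remaining mass uniform over the other
#' states; expected run length is \code{resolution / (1 - stickiness)}. Each
#' combined state determines a functional factor and a structural factor
#' (cross-product design): the functional factor drives 1D signals and gene
#' expression, the structural factor drives Hi-C affinity and loops, so the
#' two organizational layers carry complementary information by construction.
#'
#' @param genome a \linkS4class{BinnedGenome}
#' @param nFunctional number of functional states (default 3)
#' @param nStructural number of structural states (default 2)
#' @param stickiness self-transition probability in (0, 1) (default 0.9:
#'   mean run 10 bins = 1 Mb at 100 kb)
#' @param seed RNG seed
#' @return a \linkS4class{SyntheticTruth}
#' @export
plantStates <- function(genome, nFunctional = 3L, nStructural = 2L,
                        stickiness = 0.9, seed = 1L) {
    stopifnot(stickiness > 0, stickiness < 1)
    K <- nFunctional * nStructural
    n <- nbins(genome)
    if (K > n) stop("more states than bins")
    chrom <- as.integer(.binChrom(genome))
    set.seed(seed)
    combined <- integer(n)
    for (ci in unique(chrom)) {
        idx <- which(chrom == ci)
        s <- integer(length(idx))
        s[1] <- sample.int(K, 1)
        if (length(idx) > 1) for (t in 2:length(idx)) {
            if (runif(1) < stickiness) s[t] <- s[t - 1]
            else s[t] <- sample(setdiff(seq_len(K), s[t - 1]), 1)
        }
        combined[idx] <- s
    }
    new("SyntheticTruth", genome = genome, combined = combined,
        functional = as.integer((combined - 1L) %% nFunctional) + 1L,
        structural = as.integer((combined - 1L) %/% nFunctional) + 1L,
        config = list(nFunctional = as.integer(nFunctional),
                      nStructural = as.integer(nStructural),
                      stickiness = stickiness, seed = as.integer(seed)))
}

#' Simulate Hi-C contacts from planted structural states
#'
#' Poisson counts with rate \code{depth * |i - j|^(-decayExponent) *
#' affinity[s_i, s_j]} for intra-chromosomal pairs and \code{depth * 0.01 *
#' affinity[s_i, s_j]} for inter-chromosomal pairs, where s is the planted
#' structural state. Within-state affinity above between-state affinity plants
#' compartmental O/E structure; the all-ones affinity is the null.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param decayExponent power-law distance decay (default 1.0)
#' @param affinity S x S positive matrix (default: 3 on the diagonal, 1 off)
#' @param depth sequencing-depth scale (default 10)
#' @param seed RNG seed
#' @return a \linkS4class{RawContacts}
#' @export
simulateContacts <- function(truth, decayExponent = 1.0, affinity = NULL,
                             depth = 10, seed = 1L) {
    if (depth <= 0) stop("depth must be positive")
    S <- max(truth@structural)
    if (is.null(affinity)) affinity <- matrix(1, S, S) + diag(2, S)
    stopifnot(all(affinity > 0), nrow(affinity) == S)
    genome <- truth@genome
    n <- nbins(genome)
    chrom <- as.integer(.binChrom(genome))
    st <- truth@structural
    set.seed(seed)
    pieces <- list()
    ## intra per chromosome
    for (ci in unique(chrom)) {
        idx <- which(chrom == ci)
        nc <- length(idx)
        if (nc < 2) next
        pr <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
        i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
        lam <- depth * abs(j - i)^(-decayExponent) * affinity[cbind(st[i], st[j])]
        cnt <- rpois(length(lam), lam)
        keep <- cnt > 0
        pieces[[length(pieces) + 1L]] <- data.frame(i = i[keep], j = j[keep],
                                                    count = cnt[keep])
    }
    ## inter
    chrs <- unique(chrom)
    if (length(chrs) > 1) for (a in seq_along(chrs)) for (b in seq_along(chrs)) {
        if (b <= a) next
        ia <- which(chrom == chrs[a]); ib <- which(chrom == chrs[b])
        gridI <- rep(ia, times = length(ib)); gridJ <- rep(ib, each = length(ia))
        lam <- depth * 0.01 * affinity[cbind(st[gridI], st[gridJ])]
        cnt <- rpois(length(lam), lam)
        keep <- cnt > 0
        pieces[[length(pieces) + 1L]] <- data.frame(i = gridI[keep], j = gridJ[keep],
                                                    count = cnt[keep])
    }
    ed <- do.call(rbind, pieces)
    if (is.null(ed)) ed <- data.frame(i = integer(), j = integer(), count = numeric())
    makeRawContacts(ed$i, ed$j, ed$count, genome)
}

#' Simulate 1D functional signal tracks
#'
#' Per-track state means are drawn once from N(0, meanSeparation^2) keyed to
#' the planted functional states only (structural states are invisible in 1D
#' signals, which is what makes the integration comparison meaningful).
#' Emissions are Gaussian around the state mean with sd \code{noiseSd}, then
#' exponentiated so the tracks are non-negative and signal-like
#' (heavy-tailed).
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param nTracks number of tracks (default 12)
#' @param meanSeparation sd of the per-state track means (default 2;
#'   0 = no state information in the signals)
#' @param noiseSd emission noise sd (default 1)
#' @param seed RNG seed
#' @return a \linkS4class{FeatureMatrix}
#' @export
simulateSignals <- function(truth, nTracks = 12L, meanSeparation = 2,
                            noiseSd = 1, seed = 1L) {
    Fst <- max(truth@functional)
    n <- length(truth@functional)
    set.seed(seed)
    stateMeans <- matrix(rnorm(Fst * nTracks, 0, meanSeparation), Fst, nTracks)
    raw <- stateMeans[truth@functional, , drop = FALSE] +
        matrix(rnorm(n * nTracks, 0, noiseSd), n, nTracks)
    vals <- exp(raw)
    colnames(vals) <- paste0("signal_", seq_len(nTracks))
    makeFeatureMatrix(vals)
}

#' Simulate genes with state-dependent expression
#'
#' Genes are placed uniformly with lognormal lengths (median 30 kb);
#' expression is lognormal around the expression mean of the combined state of
#' the bin containing the gene midpoint.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param nGenes number of genes (default 400)
#' @param exprMeans per-combined-state expression means (RPKM scale); default
#'   geometrically spaced from 1 to 30
#' @param dispersion sd of log-expression around the state mean (default 0.5)
#' @param seed RNG seed
#' @return GRanges with mcols \code{gene_id}, \code{expression}
#' @export
simulateGenes <- function(truth, nGenes = 400L, exprMeans = NULL,
                          dispersion = 0.5, seed = 1L) {
    genome <- truth@genome
    K <- max(truth@combined)
    if (is.null(exprMeans)) exprMeans <- exp(seq(log(1), log(30), length.out = K))
    stopifnot(length(exprMeans) == K)
    lens <- genome@chromLengths
    set.seed(seed)
    chr <- sample(names(lens), nGenes, replace = TRUE, prob = lens / sum(lens))
    glen <- pmax(round(rlnorm(nGenes, log(30000), 0.75)), 200)
    start0 <- floor(runif(nGenes) * pmax(lens[chr] - glen, 1))
    end0 <- pmin(start0 + glen, lens[chr])
    midBin <- .binIndex(genome, chr, floor((start0 + end0) / 2))
    state <- truth@combined[midBin]
    expr <- rlnorm(nGenes, log(exprMeans[state]), dispersion)
    gr <- GRanges(chr, IRanges(start = start0 + 1L, end = end0))
    mcols(gr)$gene_id <- sprintf("gene_%05d", seq_len(nGenes))
    mcols(gr)$expression <- expr
    gr
}

#' Simulate ChIA-PET-like loops preferring same structural state
#'
#' With probability \code{sameStateFraction} both anchors are drawn from bins
#' of one structural state (chosen proportional to its coverage); otherwise
#' the two anchor bins are drawn independently. Anchors are 20 kb intervals
#' centered in their bin.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param nLoops number of loops (default 1000)
#' @param sameStateFraction probability in [0, 1] that a loop is same-state
#'   (default 0.9)
#' @param seed RNG seed
#' @return a \link[S4Vectors]{Pairs} of anchor GRanges
#' @export
simulateLoops <- function(truth, nLoops = 1000L, sameStateFraction = 0.9,
                          seed = 1L) {
    stopifnot(sameStateFraction >= 0, sameStateFraction <= 1)
    genome <- truth@genome
    st <- truth@structural
    S <- max(st)
    binsByState <- split(seq_along(st), st)
    set.seed(seed)
    b1 <- integer(nLoops); b2 <- integer(nLoops)
    for (r in seq_len(nLoops)) {
        if (runif(1) < sameStateFraction) {
            z <- sample.int(S, 1, prob = lengths(binsByState))
            pool <- binsByState[[z]]
            b1[r] <- pool[sample.int(length(pool), 1)]
            b2[r] <- pool[sample.int(length(pool), 1)]
        } else {
            b1[r] <- sample.int(length(st), 1)
            b2[r] <- sample.int(length(st), 1)
        }
    }
    anchor <- function(b) {
        ctr <- floor((start(genome@bins)[b] - 1 + end(genome@bins)[b]) / 2)
        GRanges(seqnames(genome@bins)[b],
                IRanges(start = pmax(ctr - 10000, 0) + 1L, end = ctr + 10000))
    }
    Pairs(anchor(b1), anchor(b2))
}

#' Generate and write a complete synthetic dataset
#'
#' Plants states, simulates contacts, signals, genes and loops, and writes
#' every format the pipeline reads (chrom.sizes, triplet contacts, one
#' bedGraph per track, genes.tsv, loops.bedpe) plus truth.json holding the
#' planted states and the full generator configuration.
#'
#' @param outdir output directory (created if needed)
#' @param chromLengths named chromosome lengths; default 2 x 50 Mb
#' @param resolution bin size (default 100 kb)
#' @param nFunctional,nStructural,stickiness see \code{\link{plantStates}}
#' @param nTracks,meanSeparation,noiseSd see \code{\link{simulateSignals}}
#' @param affinity,depth,decayExponent see \code{\link{simulateContacts}}
#' @param nGenes,nLoops,sameStateFraction see the gene and loop generators
#' @param seed master seed; stage seeds are derived from it
#' @return (invisibly) list with the truth object and all in-memory pieces
#' @export
simulateDataset <- function(outdir = NULL,
                            chromLengths = c(chrS1 = 5e7, chrS2 = 5e7),
                            resolution = 1e5,
                            nFunctional = 3L, nStructural = 2L,
                            stickiness = 0.9,
                            nTracks = 12L, meanSeparation = 2, noiseSd = 1,
                            affinity = NULL, depth = 10, decayExponent = 1.0,
                            nGenes = 400L, nLoops = 1000L,
                            sameStateFraction = 0.9, seed = 1L) {
    genome <- makeBinnedGenome(chromLengths, resolution)
    truth <- plantStates(genome, nFunctional, nStructural, stickiness,
                         seed = seed)
    contacts <- simulateContacts(truth, decayExponent, affinity, depth,
                                 seed = seed + 1L)
    signals <- simulateSignals(truth, nTracks, meanSeparation, noiseSd,
                               seed = seed + 2L)
    genes <- simulateGenes(truth, nGenes, dispersion = 0.5, seed = seed + 3L)
    loops <- simulateLoops(truth, nLoops, sameStateFraction, seed = seed + 4L)
    out <- list(genome = genome, truth = truth, contacts = contacts,
                signals = signals, genes = genes, loops = loops)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        write.table(data.frame(names(chromLengths), as.integer(chromLengths)),
                    file.path(outdir, "chrom.sizes"), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        writeContacts(contacts, genome, file.path(outdir, "contacts.txt"))
        for (j in seq_len(ncol(signals@values)))
            .writeBedGraph(signals@values[, j], genome,
                           file.path(outdir, paste0(colnames(signals@values)[j],
                                                    ".bedgraph")))
        writeGenes(genes, file.path(outdir, "genes.tsv"))
        writeLoops(loops, file.path(outdir, "loops.bedpe"))
        jsonlite::write_json(
            list(config = c(truth@config,
                            list(chromLengths = as.list(chromLengths),
                                 resolution = resolution, nTracks = nTracks,
                                 meanSeparation = meanSeparation,
                                 noiseSd = noiseSd, depth = depth,
                                 decayExponent = decayExponent,
                                 nGenes = nGenes, nLoops = nLoops,
                                 sameStateFraction = sameStateFraction,
                                 seed = seed)),
                 combined = truth@combined, functional = truth@functional,
                 structural = truth@structural),
            file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    invisible(out)
}

## per-bin values as a bedGraph (one record per bin)
.writeBedGraph <- function(values, genome, path) {
    tab <- data.frame(chrom = as.character(seqnames(genome@bins)),
                      start = start(genome@bins) - 1L,
                      end = end(genome@bins),
                      value = values)
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE, col.names = FALSE)
    invisible(path)
}
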