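#' Mask bins with poor Hi-C coverage
#'
#' Computes each bin's total raw contact marginal (sum of counts over all
#' partners, diagonal counted once) and masks bins whose marginal falls below
#' \code{minFrac} times the median marginal of their chromosome. A chromosome
#' with zero total contacts is fully masked with a warning.
#'
#' @param contacts a \linkS4class{RawContacts}
#' @param genome the \linkS4class{BinnedGenome}
#' @param minFrac fraction of the per-chromosome median marginal below which a
#'   bin is masked (default 0.25)
#' @return logical vector, TRUE = bin kept
#' @export
filterBins <- function(contacts, genome, minFrac = 0.25) {
    n <- nbins(genome)
    e <- contacts@entries
    marg <- numeric(n)
    if (nrow(e)) {
        a <- tapply(e$count, e$i, sum)
        marg[as.integer(names(a))] <- marg[as.integer(names(a))] + as.numeric(a)
        off <- e[e$i != e$j, , drop = FALSE]
        if (nrow(off)) {
            b <- tapply(off$count, off$j, sum)
            marg[as.integer(names(b))] <- marg[as.integer(names(b))] + as.numeric(b)
        }
    }
    chrom <- .binChrom(genome)
    keep <- logical(n)
    for (chr in levels(chrom)) {
        idx <- which(chrom == chr)
        if (sum(marg[idx]) == 0) {
            warning("chromosome ", chr, " has zero total contacts; all its bins masked")
            next
        }
        keep[idx] <- marg[idx] >= minFrac * median(marg[idx])
    }
    keep
}

#' Build the observed/expected interaction graph
#'
#' For each intra-chromosomal bin pair the expected count is the mean observed
#' count over all unmasked pairs of the same chromosome at the same bin
#' distance (zeros included; distance strata with fewer than \code{minPairs}
#' unmasked pairs are pooled with the adjacent longer-distance stratum). For
#' inter-chromosomal pairs the expected is the single genome-wide mean over
#' unmasked inter pairs. The edge weight is observed/expected; edges are kept
#' when the weight is at least \code{threshold} (and positive). The diagonal
#' is excluded.
#'
#' @param contacts a \linkS4class{RawContacts}
#' @param genome the \linkS4class{BinnedGenome}
#' @param mask logical per-bin mask (TRUE = keep), e.g. from
#'   \code{\link{filterBins}}; default all bins
#' @param threshold minimum O/E weight for a kept edge (default 1.0; 0 keeps
#'   every non-zero-weight pair)
#' @param minPairs minimum unmasked pairs per distance stratum before pooling
#'   (default 10)
#' @return a \linkS4class{ContactGraph} whose nodes are the unmasked bins
#' @export
computeOE <- function(contacts, genome, mask = NULL, threshold = 1.0,
                      minPairs = 10L) {
    n <- nbins(genome)
    if (is.null(mask)) mask <- rep(TRUE, n)
    stopifnot(length(mask) == n)
    e <- contacts@entries
    keepE <- mask[e$i] & mask[e$j] & e$i != e$j
    e <- e[keepE, , drop = FALSE]
    chrom <- .binChrom(genome)
    chromOf <- as.integer(chrom)
    sameChr <- chromOf[e$i] == chromOf[e$j]

    edges <- vector("list", length(levels(chrom)) + 1L)

    ## intra: per chromosome, distance-stratified expected
    for (ci in seq_along(levels(chrom))) {
        idx <- which(chromOf == ci)
        m <- mask[idx]
        nc <- length(idx)
        if (nc < 2L || !any(m)) next
        ## unmasked pair count at each distance d
        pairCount <- vapply(seq_len(nc - 1L), function(d)
            sum(m[seq_len(nc - d)] & m[seq_len(nc - d) + d]), numeric(1))
        ec <- e[sameChr & chromOf[e$i] == ci, , drop = FALSE]
        d <- ec$j - ec$i
        obsSum <- vapply(seq_len(nc - 1L), function(dd)
            sum(ec$count[d == dd]), numeric(1))
        ## pool short strata into the adjacent longer-distance stratum
        stratum <- integer(nc - 1L)
        cur <- 1L; accum <- 0
        for (dd in seq_len(nc - 1L)) {
            stratum[dd] <- cur
            accum <- accum + pairCount[dd]
            if (accum >= minPairs) { cur <- cur + 1L; accum <- 0 }
        }
        if (accum > 0 && cur > 1L)  # trailing short group merges backward
            stratum[stratum == cur] <- cur - 1L
        sPairs <- tapply(pairCount, stratum, sum)
        sObs <- tapply(obsSum, stratum, sum)
        expected <- as.numeric(sObs / sPairs)[stratum]  # per-distance expected
        zeroStrata <- unique(stratum[expected == 0 & pairCount > 0])
        if (length(zeroStrata))
            warning("chromosome ", levels(chrom)[ci], ": ", length(zeroStrata),
                    " pooled distance stratum/strata with zero expected; no edges there")
        if (nrow(ec)) {
            w <- ifelse(expected[d] > 0, ec$count / expected[d], 0)
            keep <- w >= threshold & w > 0
            edges[[ci]] <- data.frame(i = ec$i[keep], j = ec$j[keep], w = w[keep])
        }
    }

    ## inter: single global expected
    nUnmaskedPerChrom <- vapply(seq_along(levels(chrom)), function(ci)
        sum(mask[chromOf == ci]), numeric(1))
    tot <- sum(nUnmaskedPerChrom)
    interPairs <- (tot^2 - sum(nUnmaskedPerChrom^2)) / 2
    ei <- e[!sameChr, , drop = FALSE]
    if (interPairs > 0 && nrow(ei)) {
        eInter <- sum(ei$count) / interPairs
        if (eInter > 0) {
            w <- ei$count / eInter
            keep <- w >= threshold & w > 0
            edges[[length(edges)]] <- data.frame(i = ei$i[keep], j = ei$j[keep],
                                                 w = w[keep])
        }
    }

    ed <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
    if (is.null(ed)) ed <- data.frame(i = integer(), j = integer(), w = numeric())
    ed <- ed[order(ed$i, ed$j), , drop = FALSE]
    rownames(ed) <- NULL
    new("ContactGraph", edges = ed, nodes = which(mask), nbins = n)
}

#' Summary diagnostics for a contact graph
#'
#' @param graph a \linkS4class{ContactGraph}
#' @return list with node and edge counts and weight/degree quantiles
#' @export
graphStats <- function(graph) {
    e <- graph@edges
    if (!nrow(e))
        return(list(nodes = length(graph@nodes), edges = 0L,
                    weightQuantiles = rep(0, 5), degreeQuantiles = rep(0, 5)))
    deg <- nodeDegrees(graph)
    list(nodes = length(graph@nodes), edges = nrow(e),
         weightQuantiles = quantile(e$w, c(0, .25, .5, .75, 1)),
         degreeQuantiles = quantile(deg, c(0, .25, .5, .75, 1)))
}

#' Write a graph as a weighted edge list ("i j w", 1-based global bin indices)
#' @param graph a \linkS4class{ContactGraph}
#' @param path output file
#' @export
writeGraph <- function(graph, path) {
    data.table::fwrite(data.table::as.data.table(graph@edges), path, sep = " ",
                       quote = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a weighted edge list written by \code{writeGraph}
#' @param path edge-list file
#' @param nbins bin count of the underlying genome
#' @param nodes optional node set; default the union of edge endpoints
#' @return a \linkS4class{ContactGraph}
#' @export
readGraph <- function(path, nbins, nodes = NULL) {
    dt <- data.table::fread(path, header = FALSE, col.names = c("i", "j", "w"))
    ed <- as.data.frame(dt)
    if (is.null(nodes)) nodes <- sort(unique(c(ed$i, ed$j)))
    new("ContactGraph", edges = ed, nodes = as.integer(nodes),
        nbins = as.integer(nbins))
}

#' Construct a ContactGraph from an edge table
#' @param i,j node endpoints (global bin indices, any order per edge)
#' @param w positive weights
#' @param nbins total bin count
#' @param nodes node set (default union of endpoints)
#' @return a \linkS4class{ContactGraph}
#' @export
makeContactGraph <- function(i, j, w, nbins, nodes = NULL) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    ed <- data.frame(i = as.integer(lo), j = as.integer(hi), w = as.numeric(w))
    ed <- ed[order(ed$i, ed$j), , drop = FALSE]
    rownames(ed) <- NULL
    if (is.null(nodes)) nodes <- sort(unique(c(ed$i, ed$j)))
    new("ContactGraph", edges = ed, nodes = as.integer(nodes),
        nbins = as.integer(nbins))
}
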