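#' Variance explained by an annotation for a per-bin signal
#'
#' Predicts each position by its label's mean signal and reports the fraction
#' of signal variance removed by that prediction:
#' \code{VE = 1 - sum(d_i^2) / sum((s_i - mean(s))^2)} with residuals
#' \code{d_i = s_i - mu_{a_i}}. Bounded in [0, 1]. Bins missing either the
#' label or the signal are excluded. The variance convention (denominator n)
#' cancels between numerator and denominator.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param signal per-bin numeric vector, same length as the annotation
#' @return list with \code{ve}, \code{perLabelMeans}, \code{nUsed}
#' @examples
#' ann <- makeAnnotation(c(1, 1, 2, 2))
#' varianceExplained(ann, c(0, 2, 4, 6))$ve  # 0.8
#' @export
varianceExplained <- function(annotation, signal) {
    lab <- annotation@labels
    stopifnot(length(lab) == length(signal))
    use <- !is.na(lab) & !is.na(signal)
    s <- signal[use]; a <- lab[use]
    if (length(s) < 2) stop("fewer than 2 usable bins")
    ssTot <- sum((s - mean(s))^2)
    if (ssTot == 0) stop("signal has zero variance over usable bins; VE undefined")
    mu <- tapply(s, a, mean)
    pred <- as.numeric(mu[as.character(a)])
    ve <- 1 - sum((s - pred)^2) / ssTot
    muFull <- rep(NA_real_, annotation@K)
    muFull[as.integer(names(mu))] <- as.numeric(mu)
    list(ve = ve, perLabelMeans = muFull, nUsed = length(s))
}

#' Gene expression variance explained
#'
#' Each gene is annotated with the most frequent domain label among the bins
#' its interval overlaps (ties go to the lowest label index; genes overlapping
#' only unannotated bins are dropped). Expression is transformed with the
#' inverse hyperbolic sine before computing the VE over genes.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param genes GRanges with an \code{expression} metadata column (RPKM)
#' @param genome the \linkS4class{BinnedGenome}
#' @return list with \code{ve}, \code{perLabelMeans}, \code{nUsed} (genes),
#'   plus \code{geneLabels} and \code{transformedExpression} for downstream
#'   descriptive tests
#' @export
geneExpressionVE <- function(annotation, genes, genome) {
    lab <- .geneLabels(annotation, genes, genome)
    keep <- !is.na(lab)
    if (!any(keep)) stop("no gene maps to an annotated bin")
    expr <- asinh(mcols(genes)$expression[keep])
    ga <- makeAnnotation(lab[keep], K = annotation@K)
    out <- varianceExplained(ga, expr)
    out$geneLabels <- lab[keep]
    out$transformedExpression <- expr
    out
}

## majority annotation label per gene (ties -> lowest label index)
.geneLabels <- function(annotation, genes, genome) {
    hits <- findOverlaps(genes, genome@bins, ignore.strand = TRUE)
    lab <- annotation@labels[subjectHits(hits)]
    ok <- !is.na(lab)
    counts <- table(factor(queryHits(hits)[ok], levels = seq_along(genes)),
                    factor(lab[ok], levels = seq_len(annotation@K)))
    best <- apply(counts, 1, function(r) if (sum(r) == 0) NA_integer_
                  else which.max(r))  # which.max: first max = lowest label
    as.integer(best)
}

#' Replication-timing variance explained
#'
#' Coarsens fine-resolution per-phase replication-timing tracks to the working
#' resolution by within-bin averaging, renormalizes each bin's phase vector to
#' sum to one (bins with zero total mass are excluded), computes the VE for
#' each phase separately and reports their unweighted mean. A phase whose
#' coarsened track is constant has undefined VE and is excluded with a
#' warning.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param rt either a bins x phases numeric matrix of already-coarsened phase
#'   signals, or a character vector of per-phase bedGraph paths at a fine
#'   resolution dividing the working resolution
#' @param genome the \linkS4class{BinnedGenome}
#' @param nPhases declared number of phases (default 6)
#' @return list with \code{ve} (the mean), \code{perPhase}, \code{nUsed}
#' @export
replicationTimingVE <- function(annotation, rt, genome, nPhases = 6L) {
    if (is.character(rt)) {
        rt <- vapply(rt, function(p)
            featureValues(readSignalTrack(p, genome, aggregation = "mean"))[, 1],
            numeric(nbins(genome)))
    }
    rt <- as.matrix(rt)
    if (ncol(rt) != nPhases)
        stop("expected ", nPhases, " phases, got ", ncol(rt))
    tot <- rowSums(rt)
    norm <- rt
    pos <- tot > 0
    norm[pos, ] <- rt[pos, , drop = FALSE] / tot[pos]
    norm[!pos, ] <- NA_real_
    perPhase <- rep(NA_real_, nPhases)
    for (p in seq_len(nPhases)) {
        res <- tryCatch(varianceExplained(annotation, norm[, p]),
                        error = function(e) NULL)
        if (is.null(res)) {
            warning("phase ", p, " has undefined VE (constant or empty track); excluded")
        } else perPhase[p] <- res$ve
    }
    if (all(is.na(perPhase))) stop("no phase has a defined VE")
    list(ve = mean(perPhase, na.rm = TRUE), perPhase = perPhase,
         nUsed = sum(pos & !is.na(annotation@labels)))
}

#' ChIA-PET loop observed/expected enrichment
#'
#' Assigns each loop anchor to the bin containing its midpoint; loops with
#' either anchor on a masked/unannotated bin are dropped (count reported).
#' Observed counts accumulate over unordered label pairs; with label coverage
#' C the expected same-label count is \code{E_kk = totalO * C_k^2} and the
#' unordered cross-label mass \code{E_kl = 2 * totalO * C_k * C_l}, so the
#' expected matrix sums to totalO. The OE score is
#' \code{sum_k O_kk / sum_k E_kk}.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param loops a \link[S4Vectors]{Pairs} of anchor GRanges (see
#'   \code{\link{readLoops}})
#' @param genome the \linkS4class{BinnedGenome}
#' @return list with \code{oeScore}, matrices \code{observed} and
#'   \code{expected} (upper-triangle storage of unordered pairs),
#'   \code{totalO}, \code{nDropped}
#' @export
loopEnrichment <- function(annotation, loops, genome) {
    K <- annotation@K
    mid <- function(a) floor((start(a) - 1 + end(a)) / 2)  # 0-based midpoint
    b1 <- .binIndex(genome, as.character(seqnames(first(loops))), mid(first(loops)))
    b2 <- .binIndex(genome, as.character(seqnames(second(loops))), mid(second(loops)))
    l1 <- annotation@labels[b1]; l2 <- annotation@labels[b2]
    use <- !is.na(l1) & !is.na(l2)
    nDropped <- sum(!use)
    l1 <- l1[use]; l2 <- l2[use]
    totalO <- length(l1)
    if (totalO == 0) stop("no usable loops (all anchors unannotated)")
    lo <- pmin(l1, l2); hi <- pmax(l1, l2)
    O <- matrix(0, K, K)
    for (r in seq_len(totalO)) O[lo[r], hi[r]] <- O[lo[r], hi[r]] + 1
    C <- labelCoverage(annotation)
    E <- matrix(0, K, K)
    for (k in seq_len(K)) for (l in k:K)
        E[k, l] <- if (k == l) totalO * C[k]^2 else 2 * totalO * C[k] * C[l]
    list(oeScore = sum(diag(O)) / sum(diag(E)), observed = O, expected = E,
         totalO = totalO, nDropped = nDropped)
}

#' Bootstrap standard error of an annotation statistic
#'
#' Generic resampling engine: \code{statFn} receives a resampled index vector
#' into the statistic's units and returns the statistic (or NA if undefined on
#' that replicate). With \code{blockSize > 1} contiguous blocks of units are
#' resampled with replacement to the original length (the block bootstrap used
#' for per-bin statistics, default block 10 bins = 1 Mb at 100 kb); with
#' \code{blockSize = 1} units are resampled i.i.d. (genes, loops). The SE is
#' the standard deviation of the replicate statistics (denominator
#' \code{nReps - 1}). An error is raised if the statistic is undefined in more
#' than 20 percent of replicates.
#'
#' @param statFn function(indices) -> single numeric or NA
#' @param nUnits number of resampling units
#' @param nReps number of bootstrap replicates (>= 2)
#' @param blockSize block length in units (default 10)
#' @param seed RNG seed
#' @return the bootstrap SE (single numeric); the replicate values are
#'   attached as attribute \code{"replicates"}
#' @export
bootstrapSE <- function(statFn, nUnits, nReps = 100L, blockSize = 10L, seed = 1L) {
    stopifnot(nReps >= 2, nUnits >= 1, blockSize >= 1)
    set.seed(seed)
    reps <- vapply(seq_len(nReps), function(r) {
        if (blockSize == 1L) {
            idx <- sample.int(nUnits, nUnits, replace = TRUE)
        } else {
            nBlocks <- ceiling(nUnits / blockSize)
            startsAvail <- seq_len(max(nUnits - blockSize + 1L, 1L))
            starts <- sample(startsAvail, nBlocks, replace = TRUE)
            idx <- as.integer(outer(0:(blockSize - 1L), starts, `+`))
            idx <- idx[idx <= nUnits][seq_len(nUnits)]
        }
        v <- tryCatch(statFn(idx), error = function(e) NA_real_)
        if (is.null(v) || !is.finite(v)) NA_real_ else v
    }, numeric(1))
    if (mean(is.na(reps)) > 0.2)
        stop("statistic undefined in more than 20% of bootstrap replicates")
    se <- sd(reps, na.rm = TRUE)
    attr(se, "replicates") <- reps
    se
}

#' Fold-change overlap and ARI between two annotations
#'
#' Over bins annotated in both: \code{foldChange[ka, kb] = P(a = ka, b = kb) /
#' (P(a = ka) P(b = kb))} and the adjusted Rand index between the label
#' vectors.
#'
#' @param a,b \linkS4class{DomainAnnotation} objects over the same genome
#' @return list with \code{foldChange} (K_a x K_b matrix) and \code{ari}
#' @export
annotationOverlap <- function(a, b) {
    joint <- !is.na(a@labels) & !is.na(b@labels)
    if (!any(joint)) stop("annotations have no jointly annotated bins")
    la <- a@labels[joint]; lb <- b@labels[joint]
    n <- length(la)
    tab <- table(factor(la, levels = seq_len(a@K)),
                 factor(lb, levels = seq_len(b@K))) / n
    pa <- rowSums(tab); pb <- colSums(tab)
    fc <- tab / outer(pa, pb)
    fc[!is.finite(fc)] <- 0
    fc <- matrix(as.numeric(fc), a@K, b@K)
    list(foldChange = fc, ari = mclust::adjustedRandIndex(la, lb))
}

#' Domain length distribution of an annotation
#'
#' Run lengths of constant labels in bp (runs break at chromosome boundaries
#' and unannotated bins).
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param genome the \linkS4class{BinnedGenome}
#' @return list with \code{meanBp}, \code{quartilesBp}, \code{nDomains}
#' @export
domainLengths <- function(annotation, genome) {
    lab <- annotation@labels
    chrom <- as.integer(.binChrom(genome))
    w <- width(genome@bins)
    key <- paste(chrom, ifelse(is.na(lab), NA, lab))
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- !is.na(lab[starts])
    lens <- vapply(which(keep), function(q) sum(w[starts[q]:ends[q]]), numeric(1))
    if (!length(lens)) stop("annotation has no annotated runs")
    list(meanBp = mean(lens),
         quartilesBp = quantile(lens, c(0.25, 0.5, 0.75)),
         nDomains = length(lens))
}

#' Evaluate an annotation against all available inputs
#'
#' Computes every applicable statistic: the domain-length distribution
#' (always); per-track VE for supplied signals; gene expression VE;
#' replication-timing VE; loop OE per loop set; pairwise Welch t-tests of
#' transformed expression between label pairs when genes are supplied
#' (descriptive, no multiple-testing correction). Missing inputs are skipped
#' with a note. Optionally writes the report as JSON.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param genome the \linkS4class{BinnedGenome}
#' @param signals optional \linkS4class{FeatureMatrix} of per-bin signals
#' @param genes optional gene GRanges (see \code{\link{readGenes}})
#' @param rt optional replication-timing input (see
#'   \code{\link{replicationTimingVE}})
#' @param loops optional named list of \link[S4Vectors]{Pairs} loop sets
#' @param reportPath optional path for the JSON report
#' @return the report as a list
#' @export
evaluateAnnotation <- function(annotation, genome, signals = NULL,
                               genes = NULL, rt = NULL, loops = NULL,
                               reportPath = NULL) {
    report <- list(schema = "hicdomains-report/1",
                   K = annotation@K,
                   coverage = as.numeric(labelCoverage(annotation)),
                   domainLengths = domainLengths(annotation, genome),
                   notes = character())
    if (!is.null(signals)) {
        ves <- lapply(seq_len(ncol(signals@values)), function(j) {
            sig <- signals@values[, j]
            sig[!signals@mask] <- NA
            tryCatch(varianceExplained(annotation, sig)$ve,
                     error = function(e) NA_real_)
        })
        report$signalVE <- stats::setNames(ves, trackNames(signals))
    } else report$notes <- c(report$notes, "no signals supplied")
    if (!is.null(genes)) {
        gv <- geneExpressionVE(annotation, genes, genome)
        report$geneExpressionVE <- gv$ve
        report$geneTTests <- .exprTTests(gv)
    } else report$notes <- c(report$notes, "no genes supplied")
    if (!is.null(rt)) {
        rv <- replicationTimingVE(annotation, rt, genome)
        report$rtVE <- rv$ve
        report$rtPerPhaseVE <- rv$perPhase
    } else report$notes <- c(report$notes, "no replication timing supplied")
    if (!is.null(loops)) {
        if (is(loops, "Pairs")) loops <- list(loops = loops)
        report$loopOE <- lapply(loops, function(lp)
            loopEnrichment(annotation, lp, genome)$oeScore)
    } else report$notes <- c(report$notes, "no loops supplied")
    if (!is.null(reportPath)) {
        jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, force = TRUE)
    }
    report
}

## Welch t-tests of transformed expression between every label pair
.exprTTests <- function(gv) {
    labs <- sort(unique(gv$geneLabels))
    out <- list()
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
        if (j <= i) next
        xi <- gv$transformedExpression[gv$geneLabels == labs[i]]
        xj <- gv$transformedExpression[gv$geneLabels == labs[j]]
        if (length(xi) < 2 || length(xj) < 2) next
        tt <- tryCatch(stats::t.test(xi, xj), error = function(e) NULL)
        if (!is.null(tt))
            out[[paste0(labs[i], "_vs_", labs[j])]] <-
                list(t = unname(tt$statistic), p = tt$p.value)
    }
    out
}
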