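#' Build the binned coordinate system
#'
#' Tiles each chromosome with contiguous fixed-width bins (0-based half-open;
#' the last bin of a chromosome may be short). Global bin indices run
#' 1..nbins in chromosome declaration order.
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (name, length), or the path to a chrom.sizes file
#' @param resolution bin width in bp (default 100000)
#' @return a \linkS4class{BinnedGenome}
#' @examples
#' g <- makeBinnedGenome(c(chr1 = 250e3), resolution = 1e5)
#' nbins(g)  # 3
#' @export
makeBinnedGenome <- function(chromSizes, resolution = 100000L) {
    if (is.character(chromSizes) && length(chromSizes) == 1L) {
        tab <- read.table(chromSizes, header = FALSE, stringsAsFactors = FALSE)
        chromSizes <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
    } else if (is.data.frame(chromSizes)) {
        chromSizes <- stats::setNames(as.numeric(chromSizes[[2]]), as.character(chromSizes[[1]]))
    }
    resolution <- as.integer(resolution)
    if (is.na(resolution) || resolution <= 0L) stop("resolution must be a positive integer")
    if (anyDuplicated(names(chromSizes))) stop("duplicate chromosome names")
    if (any(chromSizes <= 0)) stop("chromosome sizes must be positive")
    grl <- lapply(names(chromSizes), function(chr) {
        len <- chromSizes[[chr]]
        starts <- seq(0, len - 1, by = resolution)
        ends <- pmin(starts + resolution, len)
        GRanges(chr, IRanges(start = starts + 1L, end = ends))
    })
    bins <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlevels(bins) <- names(chromSizes)
    suppressWarnings(GenomeInfoDb::seqlengths(bins) <- chromSizes)
    new("BinnedGenome", bins = bins, resolution = resolution,
        chromLengths = chromSizes)
}

## global bin index of (chrom, 0-based position); NA outside the genome
.binIndex <- function(genome, chrom, pos) {
    res <- genome@resolution
    lens <- genome@chromLengths
    nb <- ceiling(lens / res)
    offs <- stats::setNames(cumsum(c(0, nb[-length(nb)])), names(lens))
    ci <- match(chrom, names(lens))
    local <- floor(pos / res)
    idx <- offs[ci] + local + 1L
    bad <- is.na(ci) | pos < 0 | pos >= lens[ci]
    idx[bad] <- NA_integer_
    as.integer(idx)
}

## per-bin chromosome factor in declaration order
.binChrom <- function(genome) {
    factor(as.character(seqnames(genome@bins)), levels = names(genome@chromLengths))
}

#' Read binned Hi-C contacts from sparse triplet text
#'
#' Parses whitespace- or tab-separated lines "chrom1 start1 chrom2 start2
#' count". Coordinates are snapped down to the containing bin start; the store
#' is symmetric ((i, j) kept with i <= j) and duplicate pairs are summed.
#'
#' @param path triplet text file
#' @param genome a \linkS4class{BinnedGenome} at the file's resolution
#' @return a \linkS4class{RawContacts}
#' @export
readContacts <- function(path, genome) {
    dt <- data.table::fread(path, header = FALSE, sep = " ",
                            col.names = c("chrom1", "start1", "chrom2", "start2", "count"),
                            colClasses = list(character = c(1, 3)))
    unknown <- setdiff(unique(c(dt$chrom1, dt$chrom2)), names(genome@chromLengths))
    if (length(unknown))
        stop("contacts reference chromosomes absent from the genome: ",
             paste(unknown, collapse = ", "))
    if (any(dt$count < 0)) stop("negative contact count in ", path)
    i <- .binIndex(genome, dt$chrom1, dt$start1)
    j <- .binIndex(genome, dt$chrom2, dt$start2)
    if (anyNA(i) || anyNA(j)) stop("contact coordinate outside chromosome bounds")
    makeRawContacts(i, j, dt$count, genome)
}

#' Construct RawContacts from index triplets
#'
#' @param i,j global bin indices (1-based); order within a pair is irrelevant
#' @param count non-negative counts; duplicates of the same unordered pair sum
#' @param genome the BinnedGenome
#' @return a \linkS4class{RawContacts}
#' @export
makeRawContacts <- function(i, j, count, genome) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    dt <- data.table::data.table(i = lo, j = hi, count = as.numeric(count))
    dt <- dt[, list(count = sum(count)), by = c("i", "j")]
    data.table::setorder(dt, i, j)
    new("RawContacts", entries = as.data.frame(dt), nbins = nbins(genome))
}

#' Bin a 1D signal track onto the genome
#'
#' Reads a bedGraph (or bigWig, by extension .bw/.bigWig) and aggregates it
#' into per-bin values: with \code{aggregation = "mean"} the coverage-weighted
#' mean over the bin with uncovered bases counted as 0; with \code{"sum"} the
#' sum of value x overlap length in bp. Bins with no overlapping data are 0
#' and flagged no-data. Overlapping bedGraph intervals are an error.
#'
#' @param path bedGraph or bigWig file
#' @param genome a \linkS4class{BinnedGenome}
#' @param aggregation "mean" or "sum"
#' @param name track name (defaults to the file base name)
#' @return a single-track \linkS4class{FeatureMatrix}
#' @export
readSignalTrack <- function(path, genome, aggregation = c("mean", "sum"),
                            name = NULL) {
    aggregation <- match.arg(aggregation)
    isBigWig <- grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)
    gr <- if (file.size(path) == 0) GRanges() else if (isBigWig) {
        rtracklayer::import(rtracklayer::BigWigFile(path))
    } else {
        rtracklayer::import(path, format = "bedGraph")
    }
    if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
    binSignal(gr, genome, aggregation = aggregation, name = name)
}

#' Aggregate interval signal into genome bins
#'
#' @param gr a GRanges with a numeric \code{score} column (1-based closed, as
#'   imported by rtracklayer)
#' @param genome a \linkS4class{BinnedGenome}
#' @param aggregation "mean" or "sum" (see \code{\link{readSignalTrack}})
#' @param name track name
#' @return a single-track \linkS4class{FeatureMatrix}
#' @export
binSignal <- function(gr, genome, aggregation = c("mean", "sum"), name = "signal") {
    aggregation <- match.arg(aggregation)
    n <- nbins(genome)
    vals <- numeric(n)
    nodata <- rep(TRUE, n)
    if (length(gr)) {
        if (is.null(gr$score)) stop("signal track has no score column")
        byChr <- split(gr, as.character(seqnames(gr)))
        for (chr in names(byChr)) {
            g <- byChr[[chr]]
            o <- order(start(g))
            g <- g[o]
            if (length(g) > 1L) {
                ovl <- which(start(g)[-1] <= end(g)[-length(g)])
                if (length(ovl))
                    stop("overlapping intervals in signal track on ", chr,
                         " (interval ", ovl[1] + 1L, " of the sorted track)")
            }
            byChr[[chr]] <- g
        }
        gr <- unlist(GenomicRanges::GRangesList(byChr), use.names = FALSE)
        hits <- findOverlaps(genome@bins, gr, ignore.strand = TRUE)
        if (length(hits)) {
            ov <- width(pintersect(genome@bins[queryHits(hits)], gr[subjectHits(hits)]))
            contrib <- gr$score[subjectHits(hits)] * ov
            s <- tapply(contrib, queryHits(hits), sum)
            bi <- as.integer(names(s))
            vals[bi] <- as.numeric(s)
            if (aggregation == "mean")
                vals[bi] <- vals[bi] / width(genome@bins)[bi]
            nodata[bi] <- FALSE
        }
    }
    m <- matrix(vals, ncol = 1, dimnames = list(NULL, name))
    nd <- matrix(nodata, ncol = 1, dimnames = list(NULL, name))
    new("FeatureMatrix", values = m, noData = nd, mask = rep(TRUE, n),
        preproc = list())
}

#' Combine feature tracks into one FeatureMatrix
#'
#' Column-binds single- or multi-track FeatureMatrix objects over the same
#' genome and recomputes the usable-bin mask: bins flagged no-data in at least
#' half of the tracks are masked out.
#'
#' @param ... FeatureMatrix objects with equal bin counts
#' @param maskRule fraction of no-data tracks at which a bin is masked
#'   (default 0.5)
#' @return a \linkS4class{FeatureMatrix}
#' @export
combineTracks <- function(..., maskRule = 0.5) {
    fms <- list(...)
    if (length(fms) == 1L && is.list(fms[[1]]) && !is(fms[[1]], "FeatureMatrix"))
        fms <- fms[[1]]
    stopifnot(length(fms) >= 1L)
    n <- nrow(fms[[1]]@values)
    if (!all(vapply(fms, function(f) nrow(f@values) == n, logical(1))))
        stop("all feature matrices must share the genome (equal bin counts)")
    vals <- do.call(cbind, lapply(fms, function(f) f@values))
    nd <- do.call(cbind, lapply(fms, function(f) f@noData))
    mask <- rowMeans(nd) < maskRule
    new("FeatureMatrix", values = vals, noData = nd, mask = mask, preproc = list())
}

#' Construct a FeatureMatrix from a plain matrix
#'
#' @param values bins x tracks numeric matrix (colnames become track names)
#' @param mask optional logical per-bin mask (default all TRUE)
#' @param noData optional logical matrix (default all FALSE)
#' @return a \linkS4class{FeatureMatrix}
#' @export
makeFeatureMatrix <- function(values, mask = NULL, noData = NULL) {
    if (is.null(colnames(values)))
        colnames(values) <- paste0("track_", seq_len(ncol(values)))
    if (is.null(mask)) mask <- rep(TRUE, nrow(values))
    if (is.null(noData)) noData <- matrix(FALSE, nrow(values), ncol(values),
                                          dimnames = dimnames(values))
    new("FeatureMatrix", values = values, noData = noData, mask = mask,
        preproc = list())
}

#' Read ChIA-PET loops from BEDPE
#'
#' BEDPE with at least six columns (chrom1 start1 end1 chrom2 start2 end2),
#' 0-based half-open. Anchors must lie within declared chromosome bounds.
#'
#' @param path BEDPE file
#' @param genome a \linkS4class{BinnedGenome}
#' @return a \link[S4Vectors]{Pairs} of anchor GRanges
#' @export
readLoops <- function(path, genome) {
    tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("malformed BEDPE: fewer than 6 columns in ", path)
    lens <- genome@chromLengths
    for (cc in c(1, 4)) {
        unknown <- setdiff(unique(tab[[cc]]), names(lens))
        if (length(unknown)) stop("BEDPE chromosome not in genome: ", unknown[1])
    }
    if (any(tab[[3]] > lens[tab[[1]]]) || any(tab[[6]] > lens[tab[[4]]]))
        stop("BEDPE anchor beyond chromosome bounds")
    a1 <- GRanges(tab[[1]], IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
    a2 <- GRanges(tab[[4]], IRanges(start = tab[[5]] + 1L, end = tab[[6]]))
    Pairs(a1, a2)
}

#' Write loops as BEDPE
#' @param loops a \link[S4Vectors]{Pairs} of anchor GRanges
#' @param path output file
#' @export
writeLoops <- function(loops, path) {
    a1 <- first(loops); a2 <- second(loops)
    tab <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                      as.character(seqnames(a2)), start(a2) - 1L, end(a2))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a gene/expression table
#'
#' TSV with header columns gene_id, chrom, start, end, expression (RPKM;
#' coordinates 0-based half-open).
#'
#' @param path TSV file
#' @param genome optional \linkS4class{BinnedGenome} for bounds checking
#' @return a GRanges with mcols \code{gene_id} and \code{expression}
#' @export
readGenes <- function(path, genome = NULL) {
    tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "expression")
    if (!all(need %in% names(tab)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    if (any(tab$expression < 0)) stop("expression must be non-negative")
    gr <- GRanges(tab$chrom, IRanges(start = tab$start + 1L, end = tab$end))
    mcols(gr)$gene_id <- tab$gene_id
    mcols(gr)$expression <- tab$expression
    if (!is.null(genome)) {
        lens <- genome@chromLengths
        if (!all(as.character(seqnames(gr)) %in% names(lens)))
            stop("gene on chromosome absent from genome")
        if (any(end(gr) > lens[as.character(seqnames(gr))]))
            stop("gene interval beyond chromosome bounds")
    }
    gr
}

#' Write a gene/expression table
#' @param genes GRanges with mcols gene_id and expression
#' @param path output TSV
#' @export
writeGenes <- function(genes, path) {
    tab <- data.frame(gene_id = mcols(genes)$gene_id,
                      chrom = as.character(seqnames(genes)),
                      start = start(genes) - 1L, end = end(genes),
                      expression = mcols(genes)$expression)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a domain annotation as BED4
#'
#' Adjacent bins with equal labels are merged into one record; the 4th column
#' is "label_k". Masked (NA) bins produce gaps. \code{readAnnotation} inverts
#' this exactly at the bin level.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param genome the matching \linkS4class{BinnedGenome}
#' @param path output BED file
#' @export
writeAnnotation <- function(annotation, genome, path) {
    lab <- annotation@labels
    if (length(lab) != nbins(genome)) stop("annotation/genome bin count mismatch")
    chrom <- as.character(seqnames(genome@bins))
    key <- paste(chrom, ifelse(is.na(lab), "NA", lab))
    r <- rle(key)
    endsIdx <- cumsum(r$lengths)
    startsIdx <- endsIdx - r$lengths + 1L
    keep <- !is.na(lab[startsIdx])
    tab <- data.frame(chrom = chrom[startsIdx],
                      start = start(genome@bins)[startsIdx] - 1L,
                      end = end(genome@bins)[endsIdx],
                      name = paste0("label_", lab[startsIdx]))[keep, , drop = FALSE]
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a BED4 domain annotation
#'
#' @param path BED file with 4th column "label_k" (or a bare label integer)
#' @param genome the \linkS4class{BinnedGenome}
#' @param K number of labels; default the maximum label seen
#' @return a \linkS4class{DomainAnnotation}
#' @export
readAnnotation <- function(path, genome, K = NULL) {
    tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("annotation BED must have a label column")
    labNum <- suppressWarnings(as.integer(sub("^label_", "", tab[[4]])))
    if (anyNA(labNum)) stop("could not parse labels from BED column 4")
    labels <- rep(NA_integer_, nbins(genome))
    res <- genome@resolution
    for (r in seq_len(nrow(tab))) {
        starts <- seq(tab[[2]][r], tab[[3]][r] - 1L, by = res)
        idx <- .binIndex(genome, rep(tab[[1]][r], length(starts)), starts)
        labels[idx] <- labNum[r]
    }
    if (is.null(K)) K <- max(labNum)
    new("DomainAnnotation", labels = labels, K = as.integer(K), meta = list())
}

#' Construct a DomainAnnotation from labels
#' @param labels per-bin integer labels (NA = unannotated)
#' @param K number of labels (default max observed)
#' @param meta optional provenance list
#' @return a \linkS4class{DomainAnnotation}
#' @export
makeAnnotation <- function(labels, K = NULL, meta = list()) {
    labels <- as.integer(labels)
    if (is.null(K)) K <- max(labels, na.rm = TRUE)
    new("DomainAnnotation", labels = labels, K = as.integer(K), meta = meta)
}

#' Write a FeatureMatrix as TSV (chrom, start, end, one column per track)
#'
#' Values are written with full double precision; masked bins get NA.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param genome the \linkS4class{BinnedGenome}
#' @param path output TSV
#' @export
writeFeatureTSV <- function(fm, genome, path) {
    vals <- fm@values
    vals[!fm@mask, ] <- NA_real_
    tab <- data.frame(chrom = as.character(seqnames(genome@bins)),
                      start = start(genome@bins) - 1L,
                      end = end(genome@bins),
                      vals, check.names = FALSE)
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
    invisible(path)
}

#' Read a FeatureMatrix written by \code{writeFeatureTSV}
#' @param path TSV file
#' @param genome the \linkS4class{BinnedGenome}
#' @return a \linkS4class{FeatureMatrix}
#' @export
readFeatureTSV <- function(path, genome) {
    tab <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
    vals <- as.matrix(tab[, -(1:3)])
    mask <- !apply(is.na(vals), 1, any)
    vals[is.na(vals)] <- 0
    if (nrow(vals) != nbins(genome)) stop("feature TSV / genome mismatch")
    makeFeatureMatrix(vals, mask = mask)
}

#' Write contacts as sparse triplet text
#' @param contacts a \linkS4class{RawContacts}
#' @param genome the \linkS4class{BinnedGenome}
#' @param path output file
#' @export
writeContacts <- function(contacts, genome, path) {
    e <- contacts@entries
    chrom <- as.character(seqnames(genome@bins))
    s0 <- start(genome@bins) - 1L
    dt <- data.table::data.table(chrom1 = chrom[e$i], start1 = s0[e$i],
                                 chrom2 = chrom[e$j], start2 = s0[e$j],
                                 count = e$count)
    data.table::fwrite(dt, path, sep = " ", quote = FALSE, col.names = FALSE)
    invisible(path)
}
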