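test_that("variance explained matches its brute-force oracle and edge cases", {
  ann <- makeAnnotation(c(1, 1, 2, 2))
  res <- varianceExplained(ann, c(0, 2, 4, 6))
  expect_equal(res$ve, 0.8)
  expect_equal(res$perLabelMeans, c(1, 5))

  # single label, non-constant signal -> 0; piecewise-constant -> 1
  expect_equal(varianceExplained(makeAnnotation(c(1, 1, 1)), c(1, 2, 3))$ve, 0)
  expect_equal(varianceExplained(ann, c(7, 7, -1, -1))$ve, 1)

  set.seed(21)
  for (r in 1:25) {
    n <- sample(10:500, 1)
    lab <- sample(1:sample(2:6, 1), n, replace = TRUE)
    sig <- rnorm(n)
    expect_equal(varianceExplained(makeAnnotation(lab), sig)$ve,
                 bruteForceVE(lab, sig), tolerance = 1e-10)
  }
  expect_error(varianceExplained(makeAnnotation(1L), 5), "fewer than 2")
  expect_error(varianceExplained(ann, rep(3, 4)), "zero variance")
})

test_that("VE is affine-invariant and non-decreasing under label refinement", {
  set.seed(31)
  for (r in 1:10) {
    n <- 200
    lab <- sample(1:4, n, replace = TRUE)
    sig <- rnorm(n)
    v0 <- varianceExplained(makeAnnotation(lab), sig)$ve
    expect_equal(varianceExplained(makeAnnotation(lab), 3.7 * sig - 11)$ve, v0,
                 tolerance = 1e-10)
    # split label 1 into labels 1 and 5
    lab2 <- lab
    ones <- which(lab == 1)
    lab2[sample(ones, length(ones) %/% 2)] <- 5L
    expect_gte(varianceExplained(makeAnnotation(lab2, K = 5), sig)$ve,
               v0 - 1e-12)
  }
})

test_that("gene VE uses majority labels, asinh transform, and gene-level variance", {
  g <- toyGenome(3)
  ann <- makeAnnotation(c(1, 1, 2))
  gene <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 280e3))  # bins 1,1,2
  S4Vectors::mcols(gene)$gene_id <- "g1"
  S4Vectors::mcols(gene)$expression <- 0
  expect_equal(HiCdomains:::.geneLabels(ann, gene, g), 1L)   # majority
  # tie -> lowest label index
  gene2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(50e3 + 1, 150e3))
  expect_equal(HiCdomains:::.geneLabels(makeAnnotation(c(2, 1, 1)), gene2, g), 1L)

  # equal transformed expression within label groups -> VE = 1; asinh(0) = 0
  g2 <- toyGenome(4)
  ann2 <- makeAnnotation(c(1, 1, 2, 2))
  mkGenes <- function(expr) {
    gr <- GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(1, 100e3 + 1, 200e3 + 1, 300e3 + 1) + 10,
                       c(50e3, 150e3, 250e3, 350e3)))
    S4Vectors::mcols(gr)$gene_id <- paste0("g", 1:4)
    S4Vectors::mcols(gr)$expression <- expr
    gr
  }
  res <- geneExpressionVE(ann2, mkGenes(c(0, 0, 9, 9)), g2)
  expect_equal(res$ve, 1)
  expect_equal(res$transformedExpression[1], 0)
  expect_equal(res$nUsed, 4L)
})

test_that("replication-timing VE coarsens, renormalizes and averages phases", {
  g <- toyGenome(4)
  ann <- makeAnnotation(c(1, 1, 2, 2))
  # six phases as already-coarsened tracks; phase 1 constant -> excluded
  rt <- cbind(0.5, c(0.1, 0.1, 0.3, 0.3), c(0.4, 0.4, 0.2, 0.2),
              c(0, 0, 0, 0), c(0.2, 0.3, 0.2, 0.3), c(0.3, 0.2, 0.3, 0.2))
  w <- testthat::capture_warnings(res <- replicationTimingVE(ann, rt, g))
  expect_true(all(grepl("excluded", w)) && length(w) == 2L)
  # after per-bin renormalization phases 2/3 are piecewise-constant per label
  expect_equal(res$perPhase[2], 1)
  expect_equal(res$perPhase[3], 1)
  expect_true(is.na(res$perPhase[1]) && is.na(res$perPhase[4]))
  expect_equal(res$ve, mean(res$perPhase, na.rm = TRUE))
  expect_error(replicationTimingVE(ann, rt[, 1:5], g), "phases")

  # fine-resolution bedGraph coarsening: constant value p -> p
  f <- withr::local_tempfile(fileext = ".bedgraph")
  starts <- seq(0L, 4e5 - 1e3, by = 1e3)
  write.table(data.frame("chrT", formatC(starts, format = "d"),
                         formatC(starts + 1e3, format = "d"), 0.25), f,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  fm <- readSignalTrack(f, g, aggregation = "mean")
  expect_equal(unname(featureValues(fm)[, 1]), rep(0.25, 4))
})

test_that("loop enrichment reproduces the hand example and conserves totals", {
  g <- toyGenome(10)
  ann <- makeAnnotation(rep(c(1, 2), each = 5))   # coverage (0.5, 0.5)
  mkLoops <- function(b1, b2) {
    ctr <- (b1 - 1) * 1e5 + 5e4
    ctr2 <- (b2 - 1) * 1e5 + 5e4
    S4Vectors::Pairs(
      GenomicRanges::GRanges("chrT", IRanges::IRanges(ctr - 1e3, ctr + 1e3)),
      GenomicRanges::GRanges("chrT", IRanges::IRanges(ctr2 - 1e3, ctr2 + 1e3)))
  }
  sameLab <- mkLoops(c(1, 2, 3, 4, 5, 1, 2, 6, 7, 8),
                     c(2, 3, 4, 5, 1, 3, 4, 7, 8, 9))  # all within-label
  res <- loopEnrichment(ann, sameLab, g)
  expect_equal(res$totalO, 10)
  expect_equal(sum(diag(res$expected)), 5)
  expect_equal(res$oeScore, 2)
  expect_equal(sum(res$expected), res$totalO, tolerance = 1e-9)
  expect_equal(sum(res$observed), res$totalO)

  # all cross-label -> 0; single label -> always 1
  cross <- mkLoops(1:5, 6:10)
  expect_equal(loopEnrichment(ann, cross, g)$oeScore, 0)
  expect_equal(loopEnrichment(makeAnnotation(rep(1, 10)), cross, g)$oeScore, 1)

  # random instances: expected matrix sums to totalO; permutation invariance
  set.seed(41)
  for (r in 1:5) {
    lab <- sample(1:4, 40, replace = TRUE)
    annR <- makeAnnotation(lab, K = 4)
    gR <- toyGenome(40)
    lp <- mkLoops(sample(40, 30, TRUE), sample(40, 30, TRUE))
    # rebuild on the larger genome
    resR <- loopEnrichment(annR, lp, gR)
    expect_equal(sum(resR$expected), resR$totalO, tolerance = 1e-9)
    perm <- sample(4)
    resP <- loopEnrichment(makeAnnotation(perm[lab], K = 4), lp, gR)
    expect_equal(resP$oeScore, resR$oeScore, tolerance = 1e-12)
  }
})

test_that("anchors map to midpoint bins and unannotated loops are dropped", {
  g <- toyGenome(4)
  ann <- makeAnnotation(c(1, 2, NA, 2), K = 2)
  # anchor spanning bins 1-2 with midpoint in bin 1; partner on masked bin 3
  lp <- S4Vectors::Pairs(
    GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 180e3)),
    GenomicRanges::GRanges("chrT", IRanges::IRanges(200e3 + 1, 300e3)))
  expect_error(loopEnrichment(ann, lp, g), "no usable loops")
  lp2 <- S4Vectors::Pairs(
    GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 1), c(180e3, 1e5))),
    GenomicRanges::GRanges("chrT", IRanges::IRanges(c(200e3, 300e3) + 1,
                                                    c(300e3, 400e3))))
  res <- loopEnrichment(ann, lp2, g)
  expect_equal(res$nDropped, 1L)
  expect_equal(res$totalO, 1L)
})

test_that("bootstrap SE engine: degenerate data give 0, iid mean matches theory", {
  # statistic constant across replicates -> SE 0
  se0 <- bootstrapSE(function(idx) 1.0, nUnits = 50, nReps = 20, seed = 1)
  expect_equal(as.numeric(se0), 0)

  # single-label VE replicates are all zero under block resampling
  set.seed(2)
  sig <- rnorm(200)
  lab <- rep(1L, 200)
  seVe <- bootstrapSE(function(idx)
    varianceExplained(makeAnnotation(lab[idx]), sig[idx])$ve,
    nUnits = 200, nReps = 30, blockSize = 10, seed = 3)
  expect_equal(as.numeric(seVe), 0)

  # SE of the mean of N(0,1) under iid resampling ~ 1/sqrt(n) within 20%
  set.seed(4)
  x <- rnorm(400)
  se <- bootstrapSE(function(idx) mean(x[idx]), nUnits = 400, nReps = 500,
                    blockSize = 1, seed = 5)
  expect_lt(abs(as.numeric(se) - 1 / sqrt(400)), 0.2 / sqrt(400))

  expect_error(bootstrapSE(function(idx) NA_real_, 10, nReps = 10, seed = 1),
               "undefined")
})

test_that("annotation overlap: fold-change closed forms, ARI, equivariance", {
  set.seed(51)
  lab <- sample(1:3, 300, replace = TRUE)
  ann <- makeAnnotation(lab, K = 3)
  ov <- annotationOverlap(ann, ann)
  cov <- labelCoverage(ann)
  expect_equal(diag(ov$foldChange), 1 / cov, tolerance = 1e-12)
  expect_equal(ov$foldChange[upper.tri(ov$foldChange)], rep(0, 3))
  expect_equal(ov$ari, 1)

  # independent labelings: fold changes near 1, ARI near 0
  n <- 1e5
  a <- makeAnnotation(sample(1:4, n, replace = TRUE), K = 4)
  b <- makeAnnotation(sample(1:4, n, replace = TRUE), K = 4)
  ovn <- annotationOverlap(a, b)
  expect_true(all(abs(ovn$foldChange - 1) < 0.1))
  expect_lt(abs(ovn$ari), 0.01)

  # row permutation equivariance
  perm <- c(3, 1, 2)
  annP <- makeAnnotation(perm[lab], K = 3)
  ovP <- annotationOverlap(annP, ann)
  base <- annotationOverlap(ann, ann)
  reordered <- base$foldChange
  expect_equal(ovP$foldChange[perm, ], reordered, tolerance = 1e-12)
  # ARI = 1 iff identical up to label permutation
  expect_equal(ovP$ari, 1)
  annDiff <- makeAnnotation(c(lab[-1], 3L), K = 3)
  expect_lt(annotationOverlap(annDiff, ann)$ari, 1)
})

test_that("evaluation report covers lengths, skips missing inputs, round-trips JSON", {
  g <- toyGenome(5)
  ann <- makeAnnotation(c(1, 1, 1, 2, 2))
  dl <- domainLengths(ann, g)
  expect_equal(dl$meanBp, 250e3)
  expect_equal(dl$nDomains, 2L)

  rep1 <- evaluateAnnotation(ann, g)
  expect_true(any(grepl("no signals", rep1$notes)))

  f <- withr::local_tempfile(fileext = ".json")
  sig <- makeFeatureMatrix(cbind(s1 = c(0, 1, 0, 5, 6)))
  rep2 <- evaluateAnnotation(ann, g, signals = sig, reportPath = f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$signalVE[["s1"]], rep2$signalVE[["s1"]], tolerance = 1e-12)
  expect_equal(back$domainLengths$meanBp, 250e3)
})
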