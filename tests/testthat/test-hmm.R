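test_that("preprocessing applies asinh and population z-scoring with stored constants", {
  fm <- makeFeatureMatrix(cbind(t1 = c(1, 3), t2 = c(5, 5)))
  expect_warning(out <- preprocessFeatures(fm, "zscore"), "zero-variance")
  expect_equal(unname(featureValues(out)[, 1]), c(-1, 1))   # denominator-n sd
  expect_equal(trackNames(out), "t1")

  fm2 <- makeFeatureMatrix(cbind(sig = c(0, 2, 10)))
  out2 <- preprocessFeatures(fm2, "asinh_zscore")
  manual <- asinh(c(0, 2, 10))
  manual <- (manual - mean(manual)) / sqrt(mean((manual - mean(manual))^2))
  expect_equal(unname(featureValues(out2)[, 1]), manual)

  # decode-time inputs reuse fit-time constants exactly
  raw <- makeFeatureMatrix(cbind(sig = c(1, 5, 7)))
  again <- applyPreprocess(raw, out2@preproc)
  expect_equal(again@preproc$center, out2@preproc$center)
  expect_equal(unname(featureValues(again)[, 1]),
               (asinh(c(1, 5, 7)) - out2@preproc$center) / out2@preproc$scale)
})

test_that("single-state HMM reduces to the data mean with a unit transition", {
  g <- toyGenome(100)
  set.seed(1)
  fm <- preprocessFeatures(makeFeatureMatrix(matrix(rnorm(200), 100, 2)), "none")
  m <- fitHMM(fm, g, K = 1, seed = 1)
  expect_equal(m@means[1, 1, ], unname(colMeans(featureValues(fm))), tolerance = 1e-8)
  expect_equal(m@transMat, matrix(1, 1, 1))
  ann <- decodeAnnotation(m, fm, g)
  expect_true(all(domainLabels(ann) == 1))
  expect_equal(labelCoverage(ann), 1)
})

test_that("sticky two-state data is recovered: means, transitions, decoded path", {
  set.seed(5)
  n <- 3000
  s <- integer(n); s[1] <- 1
  for (t in 2:n) s[t] <- if (runif(1) < 0.95) s[t - 1] else 3 - s[t - 1]
  x <- rnorm(n, mean = c(-3, 3)[s], sd = 1)
  g <- toyGenome(n)
  fm <- preprocessFeatures(makeFeatureMatrix(matrix(x, ncol = 1)), "none")
  m <- fitHMM(fm, g, K = 2, seed = 1)
  expect_lt(max(abs(sort(m@means[, 1, 1]) - c(-3, 3))), 0.1)
  expect_lt(max(abs(diag(m@transMat) - 0.95)), 0.03)
  ann <- decodeAnnotation(m, fm, g)
  expect_gte(mclust::adjustedRandIndex(domainLabels(ann), s), 0.9)
  # EM log-likelihood history is non-decreasing within numerical slack
  expect_true(all(diff(m@logLik) >= -1e-8 * abs(m@logLik[-1])))
  # decoding is deterministic
  expect_identical(domainLabels(decodeAnnotation(m, fm, g)), domainLabels(ann))
})

test_that("forward-backward posteriors and transition rows stay normalized", {
  set.seed(3)
  fb <- HiCdomains:::.forwardBackward(matrix(rnorm(60), 15, 4),
                                      rep(0.25, 4),
                                      matrix(0.25, 4, 4))
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-10)

  g <- toyGenome(400)
  set.seed(9)
  fm <- preprocessFeatures(
    makeFeatureMatrix(matrix(rnorm(800, rep(c(0, 4), each = 400)), 400, 2)),
    "none")
  m <- fitHMM(fm, g, K = 2, seed = 2)
  expect_equal(rowSums(m@transMat), c(1, 1), tolerance = 1e-10)
  expect_equal(sum(m@initProb), 1, tolerance = 1e-10)
})

test_that("GMM fitting agrees with an independent mixture implementation", {
  library(mclust)
  set.seed(2)
  y <- rbind(matrix(rnorm(300, -2, 0.5), ncol = 2),
             matrix(rnorm(300, 2, 0.5), ncol = 2))
  g <- toyGenome(300)
  fm <- preprocessFeatures(makeFeatureMatrix(y), "none")
  gm <- fitGMM(fm, g, K = 2, seed = 1)
  ann <- decodeAnnotation(gm, fm, g)
  mc <- Mclust(y, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(adjustedRandIndex(domainLabels(ann), mc$classification), 1)
  expect_true(all(diff(gm@logLik) >= -1e-8 * abs(gm@logLik[-1])))
})

test_that("masked bins split sequences and stay unlabeled", {
  g <- toyGenome(50)
  set.seed(4)
  mask <- rep(TRUE, 50); mask[21:25] <- FALSE
  fm <- preprocessFeatures(
    makeFeatureMatrix(matrix(rnorm(100, rep(c(-2, 2), each = 50)), 50, 2),
                      mask = mask), "none")
  runs <- HiCdomains:::.sequenceRuns(g, mask)
  expect_equal(length(runs), 2L)
  expect_equal(runs[[1]], 1:20)
  m <- fitHMM(fm, g, K = 2, seed = 1)
  ann <- decodeAnnotation(m, fm, g)
  expect_true(all(is.na(domainLabels(ann)[21:25])))
  expect_true(all(!is.na(domainLabels(ann)[mask])))
})

test_that("annotation is invariant to feature track order", {
  g <- toyGenome(300)
  set.seed(6)
  s <- rep(1:3, each = 100)
  X <- cbind(a = rnorm(300, s * 2), b = rnorm(300, -s), c = rnorm(300, 0.5 * s))
  ann1 <- annotateDomains(functional = makeFeatureMatrix(X), genome = g,
                          K = 3, seed = 2)
  ann2 <- annotateDomains(functional = makeFeatureMatrix(X[, c(3, 1, 2)]),
                          genome = g, K = 3, seed = 2)
  expect_equal(mclust::adjustedRandIndex(domainLabels(ann1),
                                         domainLabels(ann2)), 1)
})

test_that("annotateDomains with one input equals manual preprocess + fit + decode", {
  g <- toyGenome(200)
  set.seed(7)
  X <- matrix(exp(rnorm(400, rep(c(0, 2), each = 200))), 200, 2)
  fmRaw <- makeFeatureMatrix(X)
  ann <- annotateDomains(functional = fmRaw, genome = g, K = 2, seed = 3)
  fm <- preprocessFeatures(fmRaw, "asinh_zscore")
  m <- fitHMM(fm, g, K = 2, seed = 3)
  manual <- decodeAnnotation(m, fm, g)
  expect_identical(domainLabels(ann), domainLabels(manual))
  expect_equal(ann@meta$mode, "functional")
  # same seed -> identical annotation
  ann2 <- annotateDomains(functional = fmRaw, genome = g, K = 2, seed = 3)
  expect_identical(domainLabels(ann), domainLabels(ann2))
  # mask disagreement is an error
  st <- makeFeatureMatrix(X, mask = c(FALSE, rep(TRUE, 199)))
  expect_error(annotateDomains(functional = fmRaw, structural = st,
                               genome = g, K = 2), "mask disagreement")
})

test_that("relabeling orders states by enrichment with stable tie-breaks", {
  ann <- makeAnnotation(c(1, 1, 2, 2, 2))
  r <- relabelByEnrichment(ann, c(5, 5, 9, 9, 9))
  expect_identical(domainLabels(r), c(2L, 2L, 1L, 1L, 1L))

  # reference identical to the annotation: identity after its own scale
  ref <- makeAnnotation(c(2, 2, 1, 1, 1))
  r2 <- relabelByEnrichment(ann, ref)
  expect_identical(domainLabels(r2), domainLabels(ref))

  # permuting input state indices leaves the named annotation unchanged
  set.seed(12)
  lab <- sample(1:4, 200, replace = TRUE)
  track <- rnorm(200, lab)
  base <- relabelByEnrichment(makeAnnotation(lab, K = 4), track)
  for (p in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    permAnn <- makeAnnotation(p[lab], K = 4)
    rp <- relabelByEnrichment(permAnn, track)
    expect_identical(domainLabels(rp), domainLabels(base))
  }
})

test_that("mixture emissions (M = 2) raise likelihood on bimodal-emission states", {
  set.seed(1)
  n <- 1000
  s <- rep(1:2, each = n / 2)
  comp <- sample(c(-1, 1), n, TRUE)
  x <- rnorm(n, mean = ifelse(s == 1, comp * 3, 0), sd = 0.5)
  g <- toyGenome(n)
  fm <- preprocessFeatures(makeFeatureMatrix(matrix(x, ncol = 1)), "none")
  m1 <- fitHMM(fm, g, K = 2, M = 1, seed = 2)
  m2 <- fitHMM(fm, g, K = 2, M = 2, seed = 2, restarts = 2)
  expect_true(all(diff(m2@logLik) >= -1e-8 * abs(m2@logLik[-1])))
  expect_gt(tail(m2@logLik, 1), tail(m1@logLik, 1))
  expect_equal(rowSums(m2@mixWeights), c(1, 1), tolerance = 1e-10)
})
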