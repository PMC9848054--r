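test_that("second-order softmax matches direct evaluation and sums to one", {
  mk <- function(u, ctx) new("EmbeddingModel", dim = ncol(u), u = u, uCtx = ctx,
                             nodes = seq_len(nrow(u)), trained = FALSE, seed = 1L)
  # identical contexts -> uniform
  m <- mk(matrix(rnorm(8), 4, 2), matrix(1, 4, 2))
  expect_equal(secondOrderSoftmax(m, 2), rep(0.25, 4))
  # zero embedding -> uniform
  m2 <- mk(matrix(0, 5, 3), matrix(rnorm(15), 5, 3))
  expect_equal(secondOrderSoftmax(m2, 1), rep(0.2, 5))
  # logits (0, ln 2, ln 4) -> (1/7, 2/7, 4/7)
  m3 <- mk(matrix(1, 3, 1), matrix(c(0, log(2), log(4)), 3, 1))
  expect_equal(secondOrderSoftmax(m3, 1), c(1, 2, 4) / 7)
  # random models: rows sum to 1 within 1e-12
  set.seed(8)
  for (r in 1:5) {
    m4 <- mk(matrix(rnorm(24, 0, 2), 6, 4), matrix(rnorm(24, 0, 2), 6, 4))
    for (i in 1:6) {
      p <- secondOrderSoftmax(m4, i)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
})

test_that("empirical neighbor distribution normalizes edge weights by degree", {
  gr <- makeContactGraph(c(1, 1, 1), c(2, 3, 4), c(1, 2, 3), nbins = 5)
  p <- empiricalDistribution(gr, 1)
  expect_equal(unname(p[c("2", "3", "4")]), c(1, 2, 3) / 6)
  expect_equal(sum(p), 1)
  gr2 <- makeContactGraph(c(1, 1), c(2, 3), c(2, 2), nbins = 3)
  expect_equal(unname(empiricalDistribution(gr2, 1)[c("2", "3")]), c(0.5, 0.5))
  expect_equal(unname(empiricalDistribution(gr2, 2)["1"]), 1)
  gr3 <- makeContactGraph(1, 2, 1, nbins = 3, nodes = 1:3)
  expect_error(empiricalDistribution(gr3, 3), "isolated")
})

test_that("exact objective reproduces closed-form values and is linear in w", {
  g2 <- makeContactGraph(1, 2, 1, nbins = 2)
  m0 <- initEmbedding(g2, dim = 4, zeroU = TRUE)
  expect_equal(exactObjective(m0, g2), 2 * log(2), tolerance = 1e-12)

  gr <- randomGraph(10, seed = 3)
  m <- initEmbedding(gr, dim = 3, seed = 5)
  m@uCtx <- matrix(rnorm(30, 0, 0.4), 10, 3)
  gr2 <- gr; gr2@edges$w <- gr@edges$w * 2
  expect_equal(exactObjective(m, gr2), 2 * exactObjective(m, gr),
               tolerance = 1e-12)

  # near-perfect softmax: one edge, huge aligned context -> contribution ~ 0
  gBig <- makeContactGraph(1, 2, 1, nbins = 2)
  mBig <- initEmbedding(gBig, dim = 2, zeroU = TRUE)
  mBig@u <- matrix(c(10, -10, 0, 0), 2, 2)
  mBig@uCtx <- matrix(c(-10, 10, 0, 0), 2, 2)
  expect_lt(exactObjective(mBig, gBig), 1e-8)
})

test_that("analytic gradient matches central finite differences on small graphs", {
  for (seed in 1:3) {
    n <- c(6, 9, 12)[seed]
    gr <- randomGraph(n, seed = seed)
    set.seed(seed + 20)
    m <- initEmbedding(gr, dim = 3, seed = seed)
    m@u <- matrix(rnorm(n * 3, 0, 0.3), n, 3)
    m@uCtx <- matrix(rnorm(n * 3, 0, 0.3), n, 3)
    an <- exactGradient(m, gr)
    h <- 1e-6
    fd <- function(slotName) {
      M <- slot(m, slotName); G <- M * 0
      for (r in seq_len(nrow(M))) for (cc in seq_len(ncol(M))) {
        mp <- m; slot(mp, slotName)[r, cc] <- M[r, cc] + h
        mm <- m; slot(mm, slotName)[r, cc] <- M[r, cc] - h
        G[r, cc] <- (exactObjective(mp, gr) - exactObjective(mm, gr)) / (2 * h)
      }
      G
    }
    expect_lt(max(abs(fd("u") - an$du)) / max(abs(an$du)), 1e-5)
    expect_lt(max(abs(fd("uCtx") - an$dctx)) / max(abs(an$dctx)), 1e-5)
  }
})

test_that("first-order objective evaluates the logistic edge loss", {
  gr <- makeContactGraph(c(1, 2), c(2, 3), c(1, 3), nbins = 3)
  m <- initEmbedding(gr, dim = 2, zeroU = TRUE)  # all dots 0 -> sigma = 0.5
  expect_equal(firstOrderObjective(m, gr), 4 * log(2), tolerance = 1e-12)
  m@u <- matrix(5, 3, 2)                         # large positive dots -> ~0
  expect_lt(firstOrderObjective(m, gr), 1e-6)
})

test_that("training reduces the exact objective and is bit-reproducible", {
  gr <- randomGraph(30, p = 0.3, seed = 1)
  before <- exactObjective(initEmbedding(gr, dim = 4, zeroU = TRUE), gr)
  m1 <- trainEmbedding(gr, trainConfig(dim = 4, seed = 3, samples = 5e5))
  expect_lt(exactObjective(m1, gr), before)
  m2 <- trainEmbedding(gr, trainConfig(dim = 4, seed = 3, samples = 5e5))
  expect_identical(embeddings(m1), embeddings(m2))
  m3 <- trainEmbedding(gr, trainConfig(dim = 4, seed = 4, samples = 5e5))
  expect_false(identical(embeddings(m1), embeddings(m3)))
})

test_that("planted 2- and 3-block graphs are recovered by k-means on embeddings", {
  for (nBlocks in 2:3) {
    bg <- blockGraph(rep(60, nBlocks))
    m <- trainEmbedding(bg$graph, trainConfig(dim = 8, seed = 13))
    set.seed(1)
    km <- kmeans(embeddings(m), nBlocks, nstart = 10)
    expect_gte(mclust::adjustedRandIndex(km$cluster, bg$labels), 0.95)
  }
})

test_that("node relabeling leaves clustering quality essentially unchanged", {
  bg <- blockGraph(c(60, 60))
  ariOf <- function(graph, labels) {
    m <- trainEmbedding(graph, trainConfig(dim = 8, seed = 5))
    set.seed(2)
    km <- kmeans(embeddings(m), 2, nstart = 10)
    mclust::adjustedRandIndex(km$cluster, labels[graphNodes(graph)])
  }
  base <- ariOf(bg$graph, bg$labels)
  set.seed(99)
  perm <- sample(120)
  e <- graphEdges(bg$graph)
  permGraph <- makeContactGraph(perm[e$i], perm[e$j], e$w, nbins = 120)
  labPerm <- integer(120); labPerm[perm] <- bg$labels
  permuted <- ariOf(permGraph, labPerm)
  expect_lte(abs(base - permuted), 0.05)
})

test_that("exported features land at their global bin indices", {
  g <- makeBinnedGenome(c(a = 8e5), 1e5)
  u <- matrix(rnorm(5 * 8), 5, 8)
  m <- new("EmbeddingModel", dim = 8L, u = u, uCtx = u * 0,
           nodes = c(2L, 3L, 5L, 7L, 8L), trained = TRUE, seed = 1L)
  fm <- exportFeatures(m, g)
  expect_equal(trackNames(fm), paste0("struct_", 1:8))
  expect_equal(unname(featureValues(fm)[c(2, 3, 5, 7, 8), ]), u)
  expect_identical(binMask(fm), seq_len(8) %in% c(2, 3, 5, 7, 8))

  # no embedded nodes: empty rows, error-free
  m0 <- new("EmbeddingModel", dim = 8L, u = matrix(0, 0, 8),
            uCtx = matrix(0, 0, 8), nodes = integer(), trained = TRUE,
            seed = 1L)
  fm0 <- exportFeatures(m0, g)
  expect_false(any(binMask(fm0)))
})
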