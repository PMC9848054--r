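# Independent oracles and fixture builders shared across test files.

# Brute-force variance explained: explicit sums of squares, no shared code
# with varianceExplained().
bruteForceVE <- function(labels, signal) {
  use <- !is.na(labels) & !is.na(signal)
  lab <- labels[use]; s <- signal[use]
  ssTot <- 0; sbar <- sum(s) / length(s)
  for (v in s) ssTot <- ssTot + (v - sbar)^2
  ssRes <- 0
  for (k in unique(lab)) {
    sk <- s[lab == k]
    mk <- sum(sk) / length(sk)
    for (v in sk) ssRes <- ssRes + (v - mk)^2
  }
  1 - ssRes / ssTot
}

# Complete weighted block graph: within-block weight win, between btw.
blockGraph <- function(sizes, win = 10, btw = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  ed <- expand.grid(i = seq_len(n), j = seq_len(n))
  ed <- ed[ed$i < ed$j, ]
  w <- ifelse(lab[ed$i] == lab[ed$j], win, btw)
  list(graph = makeContactGraph(ed$i, ed$j, w, nbins = n), labels = lab)
}

# Random sparse weighted graph over n nodes (guaranteed connected enough
# for objective tests by including a path backbone).
randomGraph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  ed <- expand.grid(i = seq_len(n), j = seq_len(n))
  ed <- ed[ed$i < ed$j & (runif(nrow(ed)) < p | ed$j - ed$i == 1), ]
  makeContactGraph(ed$i, ed$j, runif(nrow(ed), 0.5, 3), nbins = n)
}

# One-chromosome genome with n bins at 100 kb.
toyGenome <- function(n, res = 1e5) {
  makeBinnedGenome(stats::setNames(n * res, "chrT"), res)
}

# Dense symmetric observed matrix -> brute-force O/E edge list that loops
# over every pair and every distance stratum independently of computeOE().
bruteForceOE <- function(obs, minPairs = 1) {
  n <- nrow(obs)
  out <- list()
  for (d in seq_len(n - 1)) {
    pairs <- cbind(seq_len(n - d), seq_len(n - d) + d)
    e <- mean(obs[pairs])
    if (e > 0)
      for (r in seq_len(nrow(pairs)))
        out[[length(out) + 1]] <- c(pairs[r, ], obs[pairs[r, , drop = FALSE]] / e)
  }
  do.call(rbind, out)
}
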