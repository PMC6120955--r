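# Independent oracles used across the suite.

# two-pass Pearson correlation, written out from the definition
twoPassPearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

# brute-force k=2 exemplar search: the exemplar pair maximizing the total
# similarity of every point to its better exemplar (plus the shared
# preference, constant over pairs)
bruteForceTwoExemplars <- function(S) {
  n <- nrow(S)
  best <- NULL
  bestVal <- -Inf
  for (e1 in 1:(n - 1)) {
    for (e2 in (e1 + 1):n) {
      Sx <- S
      diag(Sx) <- Inf  # exemplars always choose themselves
      val <- sum(pmax(Sx[, e1], Sx[, e2])[-c(e1, e2)])
      if (val > bestVal) {
        bestVal <- val
        best <- c(e1, e2)
      }
    }
  }
  lab <- ifelse(S[, best[1]] >= S[, best[2]], 1L, 2L)
  lab[best] <- c(1L, 2L)
  list(exemplars = best, labels = lab)
}

# block-structured similarity matrix with k well-separated planted clusters
plantedSimilarity <- function(k, perCluster, within = 0.9, between = 0,
                              noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    n <- k * perCluster
    lab <- rep(seq_len(k), each = perCluster)
    S <- matrix(between, n, n)
    for (cl in seq_len(k)) S[lab == cl, lab == cl] <- within
    S <- S + matrix(stats::rnorm(n * n, 0, noise), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 0
    list(S = S, labels = lab)
  })
}

# scaled dual-area session used by the calibration/power tests
scaledSessionSpec <- function(seed, coupling) {
  sessionSpec(seed = seed, coupling = coupling, nNeurons = c(24L, 24L),
    nTrials = 48L, kClusters = 6L, trialSpacingS = 6)
}
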