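test_that("movement-related classification separates responsive neurons", {
  withr::with_seed(41, {
    rate <- 10.8
    onsets <- 5 + 6 * (0:29)
    nF <- ceiling((max(onsets) + 5) * rate)
    t <- (seq_len(nF) - 1) / rate
    # neuron 1 fires only in movement windows; neuron 2 iid
    v <- matrix(0, 2, nF)
    for (on in onsets) {
      idx <- which(t >= on - 0.46 & t <= on + 1.85)
      v[1, idx] <- rpois(length(idx), 1.5) * rexp(length(idx))
    }
    v[2, ] <- rpois(nF, 0.3) * rexp(nF)
    mask <- classifyMovementRelated(eventMatrix(v, rate), onsets)
    expect_true(mask[1])
    expect_false(mask[2])
  })
})

test_that("window frames convert to the printed seconds at 10.8 Hz", {
  expect_equal(round(-5 / 10.8, 2), -0.46)
  expect_equal(round(20 / 10.8, 2), 1.85)
})

test_that("population matrix matches a hand computation on a toy case", {
  rate <- 10.8
  nF <- 200
  v <- matrix(0, 2, nF)
  v[1, ] <- rep(c(0, 1), 100)
  v[2, ] <- seq_len(nF) / nF
  onsets <- c(6, 12) / 1  # seconds
  ev <- eventMatrix(v, rate)
  pm <- buildPopulationMatrix(ev, onsets, moveWin = c(-2, 2), area = "A")
  # hand: z-score rows over the session, average frames onset-2..onset+2
  z <- t(apply(v, 1, function(x) (x - mean(x)) / sd(x)))
  t <- (seq_len(nF) - 1) / rate
  for (k in 1:2) {
    oi <- which.min(abs(t - onsets[k]))
    expect_equal(activityValues(pm)[, k], rowMeans(z[, (oi - 2):(oi + 2)]))
  }
  expect_equal(ncol(activityValues(pm)), 2)
  # identical trials give identical columns
  v2 <- matrix(rep(c(0, 2, 0, 0), 50), 2, 100, byrow = TRUE)
  ev2 <- eventMatrix(rbind(v2[1, ], rev(v2[1, ])), rate)
  pm2 <- buildPopulationMatrix(ev2, c(4, 4), moveWin = c(-2, 2))
  expect_equal(activityValues(pm2)[, 1], activityValues(pm2)[, 2])
})

test_that("trial similarity: CC is scale-invariant, Euclidean is not", {
  withr::with_seed(42, {
    v <- matrix(rnorm(5 * 3), 5, 3)
    v[, 2] <- 2 * v[, 1]  # scaled copy
    pm <- populationMatrix("A", v)
    S <- trialSimilarityMatrix(pm, "cc")
    expect_equal(diag(S), rep(1, 3))
    expect_equal(S[1, 2], 1)
    E <- trialSimilarityMatrix(pm, "neg_sq_euclidean")
    expect_lt(E[1, 2], 0)
    expect_equal(E[1, 1], 0)
    # brute-force formulas on a 3-trial toy
    for (a in 1:2) for (b in (a + 1):3) {
      expect_equal(S[a, b], twoPassPearson(v[, a], v[, b]), tolerance = 1e-12)
      expect_equal(E[a, b], -sum((v[, a] - v[, b])^2), tolerance = 1e-9)
    }
  })
})

test_that("affinity propagation recovers well-separated planted clusters", {
  ps <- plantedSimilarity(k = 3, perCluster = 8, seed = 43)
  cl <- affinityPropagation(ps$S)
  expect_equal(nClusters(cl), 3)
  expect_equal(adjustedRand(clusterLabels(cl), ps$labels), 1)
  expect_true(cl@converged)
  # exemplars label themselves
  expect_equal(clusterLabels(cl)[cl@exemplars], seq_len(nClusters(cl)))
})

test_that("affinity propagation matches the brute-force exemplar search at k=2", {
  for (s in 1:5) {
    ps <- plantedSimilarity(k = 2, perCluster = 5, within = 0.8,
      between = 0.05, noise = 0.05, seed = 50 + s)
    # preference low enough to favor two exemplars
    cl <- affinityPropagation(ps$S, preference = min(ps$S))
    expect_equal(nClusters(cl), 2)
    oracle <- bruteForceTwoExemplars(ps$S)
    # the partition must agree; the exemplar within a cluster may differ
    # between message passing and the enumeration when members near-tie
    expect_equal(adjustedRand(clusterLabels(cl), oracle$labels), 1)
  }
})

test_that("AP is invariant to adding a constant to all similarities", {
  ps <- plantedSimilarity(k = 3, perCluster = 6, seed = 61)
  c1 <- affinityPropagation(ps$S)
  c2 <- affinityPropagation(ps$S + 5)
  expect_equal(clusterLabels(c1), clusterLabels(c2))
  expect_equal(c1@exemplars, c2@exemplars)
})

test_that("cluster count is non-increasing as the preference percentile drops", {
  withr::with_seed(62, {
    v <- matrix(rnorm(20 * 40), 20, 40)
    S <- trialSimilarityMatrix(populationMatrix("A", v), "cc")
    ks <- vapply(c(0.70, 0.30, 0.10, 0.01), function(p)
      nClusters(affinityPropagation(S, preference = list(percentile = p))),
      integer(1))
    expect_true(all(diff(ks) <= 0))
  })
})

test_that("cross-area intra-cluster CC is self-consistent and nulls correctly", {
  ps <- plantedSimilarity(k = 3, perCluster = 6, seed = 63)
  withr::with_seed(64, {
    v <- matrix(rnorm(10 * 18), 10, 18)
    pm <- populationMatrix("A", v)
    S <- trialSimilarityMatrix(pm, "cc")
    cl <- affinityPropagation(S, preference = "median")
    res <- crossAreaIntraClusterCC(cl, pm, nShuffles = 200, seed = 1)
    # self-consistency: statistic equals the same-area intra-cluster CC
    CCmat <- trialSimilarityMatrix(pm, "cc")
    vals <- c()
    for (c2 in unique(clusterLabels(cl))) {
      m <- which(clusterLabels(cl) == c2)
      if (length(m) < 2) next
      sub <- CCmat[m, m]
      vals <- c(vals, mean(sub[upper.tri(sub)]))
    }
    expect_equal(res$intraCC, mean(vals), tolerance = 1e-12)
    expect_length(res$nullValues, 200)
    # identical vectors grouped by their own clusters give intra CC 1
    ident <- matrix(rnorm(8), 8, 6)
    pmI <- populationMatrix("A", ident)
    labs <- new("ClusterResult", labels = rep(1:2, each = 3L),
      exemplars = c(1L, 4L), k = 2L, similarity = "cc", preference = 0,
      damping = 0.9, iterations = 1L, converged = TRUE)
    resI <- crossAreaIntraClusterCC(labs, pmI, nShuffles = 10, seed = 1)
    expect_equal(resI$intraCC, 1, tolerance = 1e-9)
  })
})

test_that("inter-cluster distances and agreement behave on toys", {
  withr::with_seed(65, {
    means <- matrix(rnorm(6 * 3), 6, 3)
    v <- cbind(means[, 1], means[, 1], means[, 2], means[, 2],
      means[, 3], means[, 3])
    pm <- populationMatrix("A", v)
    cl <- new("ClusterResult", labels = rep(1:3, each = 2L),
      exemplars = c(1L, 3L, 5L), k = 3L, similarity = "cc", preference = 0,
      damping = 0.9, iterations = 1L, converged = TRUE)
    D <- interClusterDistances(pm, cl, "cc")
    expect_equal(diag(D), rep(1, 3))
    expect_equal(D, t(D))
    for (a in 1:2) for (b in (a + 1):3)
      expect_equal(D[a, b], twoPassPearson(means[, a], means[, b]))
    E <- interClusterDistances(pm, cl, "euclidean")
    expect_equal(diag(E), rep(0, 3))
    # agreement of a matrix with itself / its negation
    expect_equal(clusterDistanceAgreement(D, D)$r, 1)
    expect_equal(clusterDistanceAgreement(D, -D)$r, -1)
    expect_error(clusterDistanceAgreement(D[1:2, 1:2], D[1:2, 1:2]),
      "at least 3")
  })
})

test_that("behavioral archetypes are recovered and uninformative behavior explains less", {
  # two archetypes duplicated across trials: exact recovery
  arch <- data.frame(
    pullSpeed = rep(c(10, 30), each = 8),
    leverCorrelation = rep(c(0.95, 0.7), each = 8),
    reactionTime = rep(c(0.15, 0.4), each = 8),
    timeFromPrevReward = rep(c(4, 12), each = 8)
  )
  withr::with_seed(66, {
    jit <- arch + matrix(rnorm(nrow(arch) * 4, 0, 0.01), ncol = 4) *
      rep(c(1, 0.01, 0.01, 1), each = nrow(arch))
    bc <- behaviorPropertyClusters(jit, kind = "neg_sq_euclidean")
    expect_equal(nClusters(bc$clusters), 2)
    expect_equal(adjustedRand(clusterLabels(bc$clusters),
      rep(1:2, each = 8)), 1)
  })
  # behavior decoupled from activity clusters: behavior-dependent grouping
  # explains less target-area correlation than activity-dependent grouping
  s <- simulateDualAreaSession(scaledSessionSpec(seed = 67, coupling = 0.8),
    traces = FALSE)
  res <- resampleSessionEvents(s)
  pmR <- suppressMessages(buildPopulationMatrix(res$rfa, s$onsets, area = "RFA"))
  pmC <- suppressMessages(buildPopulationMatrix(res$cfa, s$onsets, area = "CFA"))
  S <- trialSimilarityMatrix(pmR, "cc")
  clAct <- affinityPropagation(S)
  withr::with_seed(68, {
    behav <- data.frame(pullSpeed = rnorm(ncol(activityValues(pmR)), 20, 5),
      leverCorrelation = rnorm(ncol(activityValues(pmR)), 0.88, 0.02),
      reactionTime = runif(ncol(activityValues(pmR)), 0.1, 0.5),
      timeFromPrevReward = runif(ncol(activityValues(pmR)), 2, 15))
  })
  clBeh <- behaviorPropertyClusters(behav, kind = "neg_sq_euclidean")$clusters
  ccAct <- crossAreaIntraClusterCC(clAct, pmC, nShuffles = 100, seed = 1)
  ccBeh <- crossAreaIntraClusterCC(clBeh, pmC, nShuffles = 100, seed = 1)
  expect_gt(ccAct$intraCC, ccBeh$intraCC)
})

test_that("all trials identical collapse to a single behavioral cluster", {
  same <- data.frame(pullSpeed = rep(20, 10), leverCorrelation = rep(0.9, 10),
    reactionTime = rep(0.2, 10), timeFromPrevReward = rep(5, 10))
  bc <- behaviorPropertyClusters(same, kind = "neg_sq_euclidean")
  expect_equal(nClusters(bc$clusters), 1)
})
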