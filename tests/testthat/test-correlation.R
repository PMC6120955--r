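test_that("correlation table agrees with a two-pass Pearson oracle", {
  withr::with_seed(21, {
    v <- matrix(rpois(5 * 200, 0.3) * rexp(1000), 5, 200)
    ev <- eventMatrix(v, 30)
    tab <- filteredEventCCMatrix(ev, sigmaS = 0.1)
    f <- activityValues(gaussianFilterZeroPhase(ev, 0.1))
    for (r in seq_len(nrow(tab))) {
      expect_equal(tab$cc[r], twoPassPearson(f[tab$i[r], ], f[tab$j[r], ]),
        tolerance = 1e-10)
    }
    # self correlation 1, negated copy -1
    expect_equal(twoPassPearson(f[1, ], f[1, ]), 1, tolerance = 1e-12)
    expect_equal(twoPassPearson(f[1, ], -f[1, ]), -1, tolerance = 1e-12)
    # zero-variance unit dropped with a log entry
    v2 <- rbind(v, 0)
    tab2 <- filteredEventCCMatrix(eventMatrix(v2, 30), 0.1)
    expect_equal(attr(tab2, "dropped"), 6L)
    expect_false(any(tab2$i == 6 | tab2$j == 6))
  })
})

test_that("distance binning reports per-bin means and missing bins", {
  tab <- data.frame(i = 1:5, j = 2:6, cc = c(0.1, 0.2, 0.3, 0.8, 0.9),
    distance = c(50, 100, 200, 1100, 1150))
  b <- distanceBinnedCC(tab, 250)
  expect_equal(b$meanCC[1], mean(c(0.1, 0.2, 0.3)))
  expect_equal(b$meanCC[5], mean(c(0.8, 0.9)))
  expect_true(is.na(b$meanCC[2]))  # empty bin missing, not zero
  expect_equal(b$semCC[1], sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  # all pairs in one bin: that bin mean equals the global mean
  one <- data.frame(cc = c(0.2, 0.4), distance = c(10, 20))
  expect_equal(distanceBinnedCC(one, 250)$meanCC[1], 0.3)
})

test_that("a planted distant module produces a second peak in the binned curve", {
  # local pairs decay within 1 mm; a module at 2.3 mm carries extra coupling
  withr::with_seed(22, {
    nLocal <- 300; nModule <- 120
    dLocal <- runif(nLocal, 0, 900)
    ccLocal <- pmax(0.6 * exp(-dLocal / 300) + rnorm(nLocal, 0, 0.03), -1)
    dModule <- runif(nModule, 2250, 2500)
    ccModule <- 0.35 + rnorm(nModule, 0, 0.03)
    dBg <- runif(200, 1000, 2250)
    ccBg <- rnorm(200, 0.02, 0.03)
    tab <- data.frame(cc = c(ccLocal, ccModule, ccBg),
      distance = c(dLocal, dModule, dBg))
    b <- distanceBinnedCC(tab, 250)
    peakBin <- which(b$binStart == 2250)
    expect_gt(b$meanCC[peakBin], max(b$meanCC[b$binStart >= 1000 &
      b$binStart < 2250], na.rm = TRUE))
  })
})

test_that("inter-areal comparison groups pairs and detects a planted shift", {
  withr::with_seed(23, {
    # identical distributions: p roughly uniform, mean difference near 0
    n <- 400
    tab <- data.frame(
      i = 1:n, j = n + 1:n,
      cc = rnorm(2 * n, 0.1, 0.05)[1:n],
      areaI = sample(c("RFA", "CFA", "MID"), n, TRUE),
      areaJ = sample(c("RFA", "CFA", "MID"), n, TRUE)
    )
    res <- interAreaCCCompare(tab)
    expect_true(all(res$tests$p > 1e-4))
    # planted +0.05 shift on RFA-CFA detected in most seeded runs
    hits <- vapply(1:40, function(s) {
      withr::with_seed(1000 + s, {
        g1 <- rnorm(500, 0.15, 0.2)
        g2 <- rnorm(500, 0.10, 0.2)
        tt <- data.frame(i = 1:1000, j = 1001:2000, cc = c(g1, g2),
          areaI = rep(c("RFA", "RFA"), each = 500),
          areaJ = rep(c("CFA", "MID"), each = 500))
        r <- interAreaCCCompare(tt)
        r$tests$p[1] < 0.05
      })
    }, logical(1))
    expect_gt(mean(hits), 0.9)
  })
})

test_that("correlation graph edges follow the threshold monotonically", {
  tab <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), cc = c(0.5, 0.4, 0.46))
  expect_equal(nrow(correlationGraph(tab, 0.45)), 2)
  expect_equal(nrow(correlationGraph(tab, 1.0)), 0)
  e1 <- correlationGraph(tab, 0.45)
  e2 <- correlationGraph(tab, 0.3)
  expect_true(all(paste(e1$i, e1$j) %in% paste(e2$i, e2$j)))
})

test_that("the 6.5 s.d. worked example and z-scoring of top CCs", {
  expect_equal(ccDistributionZ(0.78, 0, 0.12), 6.5)
})

test_that("soma-axon matching recovers planted parentage", {
  sa <- simulateSomaAxonSession(seed = 31)
  m <- somaAxonMatch(sa$somata, sa$boutons)
  gt <- sa$groundTruth$parentage[m$retainedBoutons]
  # every parent's boutons matched, no background bouton matched
  for (i in seq_len(nrow(m$cc))) {
    mine <- which(gt == i)
    got <- m$matches$bouton[m$matches$soma == i]
    expect_setequal(got, mine)
    # top-7 of this soma are exactly its own boutons
    expect_setequal(m$perSoma[[i]]$topK$bouton[1:7], mine)
    # parent-bouton CC cluster sits in the calibrated band
    expect_true(all(m$cc[i, mine] > 0.6 & m$cc[i, mine] < 0.9))
  }
  # background CC distribution centered near zero
  bg <- which(is.na(gt))
  expect_lt(abs(mean(m$cc[, bg])), 0.05)
  # relabeling boutons permutes but preserves the match set
  perm <- sample(nrow(activityValues(sa$boutons)))
  bPerm <- eventMatrix(activityValues(sa$boutons)[perm, , drop = FALSE],
    frameRate(sa$boutons))
  m2 <- somaAxonMatch(sa$somata, bPerm)
  expect_equal(nrow(m2$matches), nrow(m$matches))
  expect_equal(sort(round(m2$matches$cc, 10)), sort(round(m$matches$cc, 10)))
})

test_that("null soma-axon sessions produce no high z-scores", {
  mx <- vapply(1:20, function(s) {
    sa <- simulateSomaAxonSession(nParents = 2, boutonsPerParent = 0,
      nBackground = 25, durationS = 300, seed = 400 + s)
    m <- somaAxonMatch(sa$somata, sa$boutons)
    max(vapply(m$perSoma, function(p) max(p$z), numeric(1)))
  }, numeric(1))
  # far below the ~6.5 s.d. regime of true matches
  expect_lt(max(mx), 4.5)
  expect_lt(median(mx), 3)
})

test_that("sibling boutons correlate more than parent-to-unrelated pairs", {
  sa <- simulateSomaAxonSession(seed = 32)
  fb <- gaussianFilterZeroPhase(sa$boutons, 0.5)
  fs <- gaussianFilterZeroPhase(sa$somata, 0.5)
  gt <- sa$groundTruth$parentage
  vb <- activityValues(fb)
  sib <- c()
  for (p in unique(gt[!is.na(gt)])) {
    ids <- which(gt == p)
    cm <- cor(t(vb[ids, ]))
    sib <- c(sib, cm[upper.tri(cm)])
  }
  unrel <- as.vector(cor(t(activityValues(fs)), t(vb[is.na(gt), ])))
  expect_gt(min(sib), max(unrel))
})

test_that("pixel-wise seed correlation maps highlight the drawn axon", {
  sa <- simulateSomaAxonSession(nParents = 1, boutonsPerParent = 6,
    nBackground = 5, rate = 1.5, durationS = 120, movie = TRUE, seed = 33)
  cmap <- pixelwiseCorrelationMap(sa$movie, sa$seedTrace, movingAvg = 5)
  on <- cmap[sa$axonPixels]
  off <- cmap[!sa$axonPixels]
  expect_gt(median(on, na.rm = TRUE) - median(off, na.rm = TRUE), 0.4)
  # a pixel carrying the seed itself correlates near 1
  mv <- sa$movie
  mv[, 1, 1] <- sa$seedTrace
  cm2 <- pixelwiseCorrelationMap(mv, sa$seedTrace, movingAvg = 5)
  expect_gt(cm2[1, 1], 0.95)
  # zero-variance pixel maps to NA
  mv[, 2, 1] <- 1
  cm3 <- pixelwiseCorrelationMap(mv, sa$seedTrace, movingAvg = 5)
  expect_true(is.na(cm3[2, 1]))
})

test_that("independent-noise movies stay within the Fisher null", {
  withr::with_seed(34, {
    nF <- 400
    mv <- array(rnorm(nF * 10 * 10), dim = c(nF, 10, 10))
    seed <- rnorm(nF)
    cmap <- pixelwiseCorrelationMap(mv, seed, movingAvg = 5)
    # 5-frame boxcar smoothing leaves ~nF/5 effective samples; the null
    # 97.5th percentile of |CC| is about 1.96/sqrt(nEff)
    nEff <- (nF - 4) / 5
    expect_lt(quantile(abs(cmap), 0.975, na.rm = TRUE),
      2.5 * 1.96 / sqrt(nEff))
  })
})
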