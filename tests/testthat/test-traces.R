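test_that("dF/F uses the whole-series percentile baseline", {
  # constant trace -> all zeros
  tm <- traceMatrix(matrix(5, 1, 50), 30)
  expect_equal(as.vector(activityValues(computeDFF(tm))), rep(0, 50))
  # two-level trace: 8th percentile of 90% baseline frames is the low level
  tr <- c(rep(100, 90), rep(200, 10))
  d <- computeDFF(traceMatrix(matrix(tr, 1), 30))
  expect_equal(sort(unique(as.vector(activityValues(d)))), c(0, 1))
  # zero-baseline unit flagged and excluded
  m <- rbind(rep(1, 20), rep(0, 20))
  expect_warning(out <- computeDFF(traceMatrix(m, 30)), "baseline")
  expect_equal(nrow(activityValues(out)), 1)
  expect_equal(attr(out, "flagged"), "u2")
  # invariant to multiplying raw traces by a constant
  withr::with_seed(1, {
    raw <- matrix(runif(200, 50, 150), 2)
    a <- computeDFF(traceMatrix(raw, 30))
    b <- computeDFF(traceMatrix(3 * raw, 30))
    expect_equal(activityValues(a), activityValues(b))
  })
})

test_that("zero-phase Gaussian filter is lag-free, mass-conserving, symmetric", {
  n <- 301
  imp <- matrix(0, 1, n); imp[1, 151] <- 1
  ev <- eventMatrix(imp, 30)
  f <- gaussianFilterZeroPhase(ev, 0.1)
  y <- activityValues(f)[1, ]
  expect_equal(which.max(y), 151)
  # symmetric bump around the impulse
  expect_equal(y[151 + 1:10], y[151 - 1:10], tolerance = 1e-12)
  # unit-sum kernel conserves mass for an interior impulse
  expect_equal(sum(y), 1, tolerance = 1e-6)
  # cross-correlation of input and output peaks at lag zero for a train
  withr::with_seed(3, {
    tr <- matrix(0, 1, 600)
    tr[1, sample(50:550, 20)] <- rexp(20)
    fv <- activityValues(gaussianFilterZeroPhase(eventMatrix(tr, 30), 0.1))[1, ]
    ccf0 <- ccf(as.numeric(tr), fv, lag.max = 10, plot = FALSE)
    expect_equal(ccf0$lag[which.max(ccf0$acf)], 0)
  })
  expect_warning(gaussianFilterZeroPhase(eventMatrix(imp, 1), 0.1), "half a frame")
})

test_that("filtered white noise has the predicted Gaussian autocorrelation width", {
  # autocovariance of white noise through a Gaussian kernel of sd s is a
  # Gaussian with sd s*sqrt(2)
  withr::with_seed(5, {
    n <- 60000; rate <- 30; sig <- 0.1
    x <- matrix(rnorm(n), 1)
    # bypass the nonnegativity of EventMatrix: the filter is linear
    f <- gaussianFilterZeroPhase(traceMatrix(x, rate), sig)
    ac <- acf(activityValues(f)[1, ], lag.max = 15, plot = FALSE)$acf[, 1, 1]
    lags <- (0:15) / rate
    expected <- exp(-lags^2 / (2 * (sig * sqrt(2))^2))
    expect_equal(ac, expected, tolerance = 0.05)
  })
})

test_that("peak detection counts strict local maxima above 2 s.d.", {
  # flat trace: no peaks
  expect_equal(unname(detectPeakEvents(eventMatrix(matrix(1, 1, 30), 30))$counts), 0L)
  # 12 well-separated filtered impulses -> 12 peaks (brute-force check)
  tr <- matrix(0, 1, 1300)
  at <- seq(50, 1250, length.out = 12)
  tr[1, round(at)] <- 5
  f <- gaussianFilterZeroPhase(eventMatrix(tr, 30), 0.1)
  pk <- detectPeakEvents(f, 2)
  expect_equal(unname(pk$counts), 12L)
  # brute-force scan agrees
  y <- activityValues(f)[1, ]
  thr <- 2 * sd(y)
  brute <- sum(vapply(2:(length(y) - 1), function(i)
    y[i] > y[i - 1] && y[i] > y[i + 1] && y[i] > thr, logical(1)))
  expect_equal(unname(pk$counts), brute)
  # the >10 retention rule keeps 11 peaks, drops 10
  expect_true(11L > 10L && !(10L > 10L))
})

test_that("down-sampling by skipping frames", {
  withr::with_seed(2, {
    tm <- traceMatrix(matrix(rnorm(300), 3), 30)
    expect_equal(activityValues(downsampleBySkip(tm, 1)), activityValues(tm))
    d6 <- downsampleBySkip(tm, 6)
    expect_equal(frameRate(d6), 5)
    expect_equal(activityValues(d6), activityValues(tm)[, seq(1, 100, by = 6)])
    expect_equal(ncol(activityValues(downsampleBySkip(tm, 30))), 4)  # ceil(100/30)
    expect_error(downsampleBySkip(tm, 200), "exceeds")
  })
})

test_that("pairwise CC survives down-sampling of slow signals", {
  # two correlated slowly varying filtered signals: CC at 5 Hz close to CC
  # at 30 Hz (the frame-rate robustness the method depends on)
  withr::with_seed(8, {
    n <- 4000
    slow <- function() as.numeric(stats::filter(rnorm(n), rep(1, 30) / 30,
      circular = TRUE))
    cc30 <- numeric(20); cc5 <- numeric(20)
    for (p in 1:20) {
      shared <- slow()
      w <- runif(1, 0.2, 2)
      a <- shared + w * slow()
      b <- shared + w * slow()
      tm <- traceMatrix(rbind(a, b), 30)
      cc30[p] <- cor(a, b)
      d <- activityValues(downsampleBySkip(tm, 6))
      cc5[p] <- cor(d[1, ], d[2, ])
    }
    expect_gt(cor(cc30, cc5), 0.8)
  })
})

test_that("resampling onto a clock is linear interpolation without extrapolation", {
  tm <- traceMatrix(matrix(seq(0, 99), 1), 10)
  # a linear ramp resamples exactly anywhere inside the span
  out <- resampleToClock(tm, c(0.05, 1.23, 5.5))
  expect_equal(as.vector(activityValues(out)), c(0.5, 12.3, 55.0))
  # resampling onto the source clock is the identity
  same <- resampleToClock(tm, frameTimes(tm))
  expect_equal(activityValues(same), activityValues(tm))
  expect_error(resampleToClock(tm, c(5, 20)), "extrapolation")
  # two interleaved 5.4 Hz fields give a 10.8 Hz union clock
  clock <- dualFieldClock(5.4, 60)
  expect_equal(1 / mean(diff(clock)), 10.8, tolerance = 1e-6)
})

test_that("lever-period masking drops padded movement windows", {
  withr::with_seed(6, {
    rate <- 4.4
    n <- 3000
    tm <- traceMatrix(matrix(rnorm(2 * n), 2), rate)
    moves <- cbind(c(100, 300, 500.5), c(101, 302, 501))
    out <- maskLeverPeriods(tm, moves, padS = 1.0)
    t <- (seq_len(n) - 1) / rate
    # brute force per-frame test
    bad <- rep(FALSE, n)
    for (r in 1:3) bad <- bad | (t >= moves[r, 1] - 1 & t <= moves[r, 2] + 1)
    expect_equal(attr(out, "keptFrames"), which(!bad))
    expect_equal(ncol(activityValues(out)), sum(!bad))
    # no movement: identity
    idn <- maskLeverPeriods(tm, matrix(numeric(0), 0, 2))
    expect_equal(activityValues(idn), activityValues(tm))
    expect_error(maskLeverPeriods(tm, cbind(-10, 10000)), "every frame")
  })
})
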