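cfg <- deviceConfig()

test_that("center distance follows the chord formula and its printed values", {
  expect_equal(centerDistance(cfg, 180), 5.0)
  expect_equal(centerDistance(cfg, 0), 0.0)
  expect_equal(centerDistance(cfg, 60), 2.5)
  expect_equal(round(centerDistance(cfg, 177), 3), 4.998)
  # symmetric about 180 deg
  expect_equal(centerDistance(cfg, 170), centerDistance(cfg, 190))
  # monotone increasing on [0, 180], maximum exactly 2 d_mm
  th <- seq(0, 180, by = 0.5)
  expect_true(all(diff(centerDistance(cfg, th)) > 0))
  expect_equal(max(centerDistance(cfg, th)), 2 * 2.5)
  expect_error(centerDistance(cfg, -1), "theta")
  expect_error(centerDistance(cfg, 361), "theta")
})

test_that("angle_for_distance inverts center_distance", {
  expect_equal(angleForDistance(cfg, 5.0), 180)
  expect_equal(angleForDistance(cfg, 0), 0)
  expect_equal(angleForDistance(cfg, 2.5), 2 * asin(0.5) * 180 / pi)
  d <- seq(0, 5, by = 0.05)
  expect_equal(centerDistance(cfg, angleForDistance(cfg, d)), d,
    tolerance = 1e-9)
  expect_error(angleForDistance(cfg, 5.01), "maximum")
})

test_that("observable annulus bounds use the FOV half-diagonal", {
  ann <- observableAnnulus(cfg)
  expect_equal(ann$innerRadius, 2.5 - sqrt(2) / 2)
  expect_equal(ann$outerRadius, 2.5 + sqrt(2) / 2)
  expect_equal(round(ann$maxObservableDistance, 1), 6.4)
  # vanishing FOV degenerates to a circle
  tiny <- deviceConfig(fovSide = 1e-9)
  annT <- observableAnnulus(tiny)
  expect_equal(annT$innerRadius, 2.5, tolerance = 1e-6)
  expect_equal(annT$outerRadius, 2.5, tolerance = 1e-6)
})

test_that("every annulus point is reachable by some rotation angle", {
  # brute force: a lattice of points at 10 um spacing, theta on a 0.1 deg
  # grid; reachability = the point falls inside the square FOV centered at
  # the rotated position for some theta (FOV corners rotate with the device)
  ann <- observableAnnulus(cfg)
  th <- seq(0, 360, by = 0.1)
  centersX <- 2.5 * cos(th * pi / 180)
  centersY <- 2.5 * sin(th * pi / 180)
  pts <- expand.grid(x = seq(-3.3, 3.3, by = 0.25),
    y = seq(0, 3.3, by = 0.25))
  r <- sqrt(pts$x^2 + pts$y^2)
  inAnn <- r >= ann$innerRadius & r <= ann$outerRadius
  half <- 0.5
  reach <- vapply(seq_len(nrow(pts)), function(i) {
    # in the frame rotating with the device, the FOV is an axis-aligned
    # square: rotate the point back by each theta and test the box
    ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
    rx <- pts$x[i] * ct + pts$y[i] * st - 2.5
    ry <- -pts$x[i] * st + pts$y[i] * ct
    any(abs(rx) <= half & abs(ry) <= half)
  }, logical(1))
  # every reachable point lies within the annulus (annulus is an upper bound)
  expect_true(all(r[reach] <= ann$outerRadius + 1e-9))
  expect_true(all(r[reach] >= ann$innerRadius - 1e-9))
  # and annulus membership implies reachability except within a lattice
  # step of the bounds (corner-only coverage at the extremes)
  interior <- inAnn & r < ann$outerRadius - 0.25 & r > ann$innerRadius + 0.25
  expect_true(all(reach[interior]))
})

test_that("ideal dual-field rate matches the printed 6.6 Hz and decreases with dead time", {
  expect_equal(round(idealDualFieldRate(cfg, 60), 1), 6.6)
  expect_equal(round(idealDualFieldRate(cfg, 180), 2), 4.41)
  noRot <- deviceConfig(rotationTimeMs = c("0" = 0, "180" = 80))
  expect_equal(idealDualFieldRate(noRot, 0), 1000 / (2 * 33.3))
  # strictly decreasing in scan time and rotation time
  slower <- deviceConfig(scanTimeMs = 66.6)
  expect_lt(idealDualFieldRate(slower, 60), idealDualFieldRate(cfg, 60))
  expect_lt(idealDualFieldRate(cfg, 180), idealDualFieldRate(cfg, 60))
  expect_error(idealDualFieldRate(cfg, 30), "extrapolation")
})

test_that("pixel throughput is the plain product and reproduces the printed figures", {
  expect_equal(pixelThroughput(512, 512, 2, 5), 2621440)
  expect_equal(round(pixelThroughput(512, 512, 2, 5) / 1e6, 1), 2.6)
  expect_equal(round(pixelThroughput(512, 512, 4, 9.5) / 1e6, 0), 10)
  expect_equal(round(pixelThroughput(512, 256, 2, 30) / 1e6, 1), 7.9)
  expect_equal(round(pixelThroughput(512, 512, 4, 9.5) /
    pixelThroughput(512, 512, 2, 5), 1), 3.8)
  expect_equal(round(pixelThroughput(512, 256, 2, 30) /
    pixelThroughput(512, 512, 2, 5), 0), 3)
  # multiplicative, argument order irrelevant
  expect_equal(pixelThroughput(2, 3, 4, 5), pixelThroughput(5, 4, 3, 2))
})

test_that("tilt penalty and mirror aspect ratio", {
  expect_equal(round(tiltDmcDelta(8, 5), 1), 0.7)
  expect_equal(tiltDmcDelta(8, 0), 0)
  expect_equal(tiltDmcDelta(8, 30), 4.0)
  expect_equal(beamEllipticity(cfg), 1.6)
  expect_equal(beamEllipticity(deviceConfig(mirrorWidth = 2.5)), 1.0)
  expect_equal(beamEllipticity(deviceConfig(mirrorWidth = 5.0)), 2.0)
})

test_that("device config validity rejects bad geometry", {
  expect_error(deviceConfig(dMirrorMirror = -1), "positive")
  expect_error(deviceConfig(fovSide = 3), "fovSide")
  expect_error(deviceConfig(rotationTimeMs = c("60" = 80, "180" = 43)),
    "nondecreasing")
})
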