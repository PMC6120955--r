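# Closed-form calculators for the rotating post-objective mirror device.
# Angles are degrees at the interface and radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Distance between the centers of the two fields of view
#'
#' Rotating the mirror pair by theta displaces the FOV along a circle of
#' radius equal to the inter-mirror distance; the chord between the two FOV
#' centers is \code{d_mm * 2 * sin(theta / 2)}.
#'
#' @param cfg a [DeviceConfig-class].
#' @param theta rotation angle, degrees, in \code{[0, 360]}.
#' @return Center-to-center distance in mm.
#' @examples
#' centerDistance(deviceConfig(), 180)  # 5 mm
#' centerDistance(deviceConfig(), 60)   # 2.5 mm
#' @export
centerDistance <- function(cfg, theta) {
  stopifnot(is(cfg, "DeviceConfig"))
  if (any(theta < 0 | theta > 360))
    stop("theta must lie in [0, 360] degrees")
  cfg@dMirrorMirror * 2 * sin(deg2rad(theta) / 2)
}

#' Rotation angle that places two FOV centers a given distance apart
#'
#' Inverse of [centerDistance()] on the rising branch, returning an angle in
#' \code{[0, 180]} degrees.
#'
#' @param cfg a [DeviceConfig-class].
#' @param dist desired center-to-center distance, mm.
#' @return Angle in degrees.
#' @export
angleForDistance <- function(cfg, dist) {
  stopifnot(is(cfg, "DeviceConfig"))
  dmax <- 2 * cfg@dMirrorMirror
  if (any(dist < 0)) stop("dist must be nonnegative")
  if (any(dist > dmax))
    stop(sprintf("dist exceeds the maximum reachable distance of %g mm", dmax))
  rad2deg(2 * asin(dist / dmax))
}

#' Observable annulus of the rotating device
#'
#' The square FOV rotates with the device, so a corner can point radially:
#' the annulus spans the inter-mirror distance plus/minus the FOV
#' half-diagonal. A point is imageable iff its distance from the device
#' axis lies within the bounds.
#'
#' @param cfg a [DeviceConfig-class].
#' @return list with \code{innerRadius}, \code{outerRadius} (mm) and
#'   \code{maxObservableDistance = 2 * outerRadius}.
#' @examples
#' observableAnnulus(deviceConfig())  # outer ~3.207 mm, max ~6.4 mm
#' @export
observableAnnulus <- function(cfg) {
  stopifnot(is(cfg, "DeviceConfig"))
  halfDiag <- cfg@fovSide * sqrt(2) / 2
  list(
    innerRadius = cfg@dMirrorMirror - halfDiag,
    outerRadius = cfg@dMirrorMirror + halfDiag,
    maxObservableDistance = 2 * (cfg@dMirrorMirror + halfDiag)
  )
}

rotationTimeAt <- function(cfg, theta) {
  rt <- cfg@rotationTimeMs
  if (!length(rt)) stop("no rotation timings configured")
  ang <- as.numeric(names(rt))
  o <- order(ang)
  ang <- ang[o]; rt <- rt[o]
  if (theta < min(ang) || theta > max(ang))
    stop(sprintf(
      "no rotation timing for %g deg: tabulated range is [%g, %g] and extrapolation is not allowed",
      theta, min(ang), max(ang)))
  stats::approx(ang, rt, xout = theta)$y
}

#' Ideal per-field frame rate for dual-field imaging
#'
#' One dual-field cycle scans each field once and rotates twice, so the
#' per-field rate is \code{1 / (2 * (scan + rotation))}. Rotation times
#' between tabulated angles are linearly interpolated; extrapolation is an
#' error.
#'
#' @param cfg a [DeviceConfig-class].
#' @param theta rotation angle, degrees.
#' @return Rate in Hz per field.
#' @examples
#' idealDualFieldRate(deviceConfig(), 60)  # ~6.6 Hz
#' @export
idealDualFieldRate <- function(cfg, theta) {
  stopifnot(is(cfg, "DeviceConfig"))
  rot <- rotationTimeAt(cfg, theta)
  1000 / (2 * (cfg@scanTimeMs + rot))
}

#' Pixel throughput of a multi-field acquisition
#'
#' @param widthPx,heightPx frame dimensions in pixels.
#' @param nFields number of fields imaged per cycle.
#' @param perFieldRate frame rate per field, Hz.
#' @return Pixels per second (product of the four arguments).
#' @examples
#' pixelThroughput(512, 512, 2, 5)  # ~2.6 Mpixel/s
#' @export
pixelThroughput <- function(widthPx, heightPx, nFields, perFieldRate) {
  stopifnot(widthPx > 0, heightPx > 0, nFields > 0, perFieldRate > 0)
  widthPx * heightPx * nFields * perFieldRate
}

#' Extra mirror-to-coverglass distance induced by a tilted window
#'
#' A glass window of a given length set at a tilt raises one edge by
#' \code{length * sin(tilt)} relative to the other, consuming that much of
#' the working-distance budget.
#'
#' @param windowLength window length, mm.
#' @param tilt tilt angle, degrees, in \code{[0, 90)}.
#' @return Extra distance in mm.
#' @examples
#' tiltDmcDelta(8, 5)  # ~0.7 mm
#' @export
tiltDmcDelta <- function(windowLength, tilt) {
  if (any(tilt < 0 | tilt >= 90)) stop("tilt must lie in [0, 90) degrees")
  windowLength * sin(deg2rad(tilt))
}

#' Mirror aspect ratio (beam ellipticity proxy)
#'
#' @param cfg a [DeviceConfig-class].
#' @return \code{mirrorWidth / mirrorHeight}.
#' @examples
#' beamEllipticity(deviceConfig())  # 1.6
#' @export
beamEllipticity <- function(cfg) {
  stopifnot(is(cfg, "DeviceConfig"))
  cfg@mirrorWidth / cfg@mirrorHeight
}

#' Full geometry report
#'
#' Runs every calculator on a configuration and returns a plain list
#' suitable for JSON serialization.
#'
#' @param cfg a [DeviceConfig-class].
#' @param thetas angles (deg) at which to report center distances and rates.
#' @return Named list of calculator outputs.
#' @export
geometryReport <- function(cfg = deviceConfig(),
                           thetas = as.numeric(names(cfg@rotationTimeMs))) {
  ann <- observableAnnulus(cfg)
  rates <- vapply(thetas, function(th) {
    tryCatch(idealDualFieldRate(cfg, th), error = function(e) NA_real_)
  }, numeric(1))
  list(
    centerDistanceMm = stats::setNames(centerDistance(cfg, thetas),
      paste0("theta", thetas)),
    annulus = ann,
    idealDualFieldRateHz = stats::setNames(rates, paste0("theta", thetas)),
    beamEllipticity = beamEllipticity(cfg)
  )
}
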