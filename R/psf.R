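# Bead-based point-spread-function characterization: average repeated
# frames per focal plane, extract lateral and axial line profiles through
# the bead, and fit Gaussians to estimate FWHMs.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Average repeated frames per focal plane
#'
#' Bead stacks are acquired with several frames per focal plane; the
#' per-plane mean is used for all downstream profile extraction.
#'
#' @param frames 3-D array \code{[frame, y, x]} with planes contiguous
#'   (repeats innermost: frames 1..n are plane 1, and so on).
#' @param framesPerPlane repeats per plane; must divide the frame count.
#' @param voxelSize named numeric \code{c(x=, y=, z=)}, um.
#' @return A [BeadVolume-class] with depth \code{nframes / framesPerPlane}.
#' @export
averagePlaneRepeats <- function(frames, framesPerPlane = 5L,
                                voxelSize = c(x = 0.249, y = 0.249, z = 0.5)) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be a 3-D array [frame, y, x]")
  framesPerPlane <- as.integer(framesPerPlane)
  if (d[1] %% framesPerPlane != 0L)
    stop(sprintf("frame count (%d) is not divisible by framesPerPlane (%d)",
      d[1], framesPerPlane))
  nz <- d[1] %/% framesPerPlane
  vol <- array(0, dim = c(nz, d[2], d[3]))
  for (z in seq_len(nz)) {
    idx <- ((z - 1L) * framesPerPlane + 1L):(z * framesPerPlane)
    plane <- frames[idx, , , drop = FALSE]
    vol[z, , ] <- apply(plane, c(2, 3), mean)
  }
  beadVolume(vol, voxelSize = voxelSize, framesPerPlane = framesPerPlane)
}

# 3-voxel box smoothing (edge-replicated), used only for center and
# orientation estimation so stray noise voxels cannot dominate the moments
boxSmooth3d <- function(a) {
  shiftAvg <- function(a, d) {
    n <- dim(a)[d]
    i0 <- seq_len(n); im <- pmax(i0 - 1L, 1L); ip <- pmin(i0 + 1L, n)
    switch(d,
      (a[im, , , drop = FALSE] + a[i0, , , drop = FALSE] +
        a[ip, , , drop = FALSE]) / 3,
      (a[, im, , drop = FALSE] + a[, i0, , drop = FALSE] +
        a[, ip, , drop = FALSE]) / 3,
      (a[, , im, drop = FALSE] + a[, , i0, drop = FALSE] +
        a[, , ip, drop = FALSE]) / 3)
  }
  shiftAvg(shiftAvg(shiftAvg(a, 1L), 2L), 3L)
}

boxSmooth2d <- function(m) {
  sm <- function(m, byrow) {
    n <- if (byrow) nrow(m) else ncol(m)
    i0 <- seq_len(n); im <- pmax(i0 - 1L, 1L); ip <- pmin(i0 + 1L, n)
    if (byrow) (m[im, , drop = FALSE] + m[i0, , drop = FALSE] +
      m[ip, , drop = FALSE]) / 3
    else (m[, im, drop = FALSE] + m[, i0, drop = FALSE] +
      m[, ip, drop = FALSE]) / 3
  }
  sm(sm(m, TRUE), FALSE)
}

# Background level: median of the volume's border voxels.
borderBackground <- function(vol) {
  a <- vol@intensity
  d <- dim(a)
  border <- c(
    a[c(1, d[1]), , ], a[, c(1, d[2]), ], a[, , c(1, d[3])]
  )
  stats::median(border)
}

# Intensity-weighted centroid (z, y, x in voxel indices) of above-background
# signal; errors on an empty volume and warns when a second connected blob
# rivals the brightest one.
beadCentroid <- function(vol, bg) {
  sm <- boxSmooth3d(vol@intensity)
  a <- sm - bg
  a[a < 0] <- 0
  d <- dim(sm)
  borderSd <- stats::mad(c(sm[c(1, d[1]), , ], sm[, c(1, d[2]), ],
    sm[, , c(1, d[3])]))
  if (max(a) <= max(8 * borderSd, 0))
    stop("no voxel above the background threshold: the volume contains no bead")
  thr <- 0.2 * max(a)
  mask <- a >= thr
  w <- a * mask
  idx <- which(mask, arr.ind = TRUE)
  tot <- sum(w)
  ctr <- colSums(idx * w[mask]) / tot
  # dominance check: bright voxels far from the centroid indicate a rival bead
  dists <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
    (idx[, 3] - ctr[3])^2)
  span <- max(dim(a)) / 8
  far <- w[mask][dists > span]
  if (length(far) && max(far) > 0.8 * max(a))
    warning("multiple comparable-intensity beads detected; dominance assumption violated")
  ctr
}

#' Extract lateral and axial line profiles through a bead
#'
#' The plane with the maximum mean intensity provides single-line X and Y
#' profiles through the intensity-weighted bead centroid. XZ and YZ
#' sections through the centroid provide axial profiles, sampled along the
#' direction in which the bead is elongated (the principal axis of the
#' above-background intensity in the section), with bilinear interpolation
#' at uniform physical spacing because axial sections are anisotropic.
#'
#' @param vol a [BeadVolume-class] containing one dominant bead.
#' @return list of profiles; each has \code{position} (um), \code{intensity},
#'   and for axial profiles \code{angleDeg}, the elongation angle from the
#'   z-axis.
#' @export
extractProfiles <- function(vol) {
  a <- vol@intensity
  vs <- vol@voxelSize
  bg <- borderBackground(vol)
  ctr <- beadCentroid(vol, bg)  # (z, y, x)
  planeMeans <- apply(boxSmooth3d(a), 1, mean)
  zBest <- which.max(planeMeans)
  yc <- round(ctr[2]); xc <- round(ctr[3])

  profX <- list(position = (seq_len(dim(a)[3]) - 1) * vs["x"],
    intensity = a[zBest, yc, ])
  profY <- list(position = (seq_len(dim(a)[2]) - 1) * vs["y"],
    intensity = a[zBest, , xc])

  profXZ <- axialSectionProfile(a[, yc, ], vs["x"], vs["z"], bg)

  profYZ <- axialSectionProfile(a[, , xc], vs["y"], vs["z"], bg)

  list(x = profX, y = profY, axialXZ = profXZ, axialYZ = profYZ)
}

# sec: matrix [z, lateral]; returns profile through the weighted centroid
# along the section's principal (elongation) axis at uniform spacing.
axialSectionProfile <- function(sec, latVox, zVox, bg) {
  s <- boxSmooth2d(sec) - bg
  s[s < 0] <- 0
  # physical coordinates of each pixel center
  nz <- nrow(s); nl <- ncol(s)
  zpos <- (seq_len(nz) - 1) * zVox
  lpos <- (seq_len(nl) - 1) * latVox
  w <- s
  thr <- 0.2 * max(w)
  w[w < thr] <- 0
  w <- w^2  # squared weights suppress stray noise pixels in the moments
  tot <- sum(w)
  if (tot <= 0) stop("empty axial section")
  Z <- matrix(zpos, nz, nl)
  L <- matrix(lpos, nz, nl, byrow = TRUE)
  zc <- sum(Z * w) / tot
  lc <- sum(L * w) / tot
  # second central moments -> principal axis
  mzz <- sum((Z - zc)^2 * w) / tot
  mll <- sum((L - lc)^2 * w) / tot
  mzl <- sum((Z - zc) * (L - lc) * w) / tot
  ang <- 0.5 * atan2(2 * mzl, mzz - mll)  # angle of major axis from z
  dirz <- cos(ang); dirl <- sin(ang)
  # sample along the line through (zc, lc) with bilinear interpolation
  step <- min(zVox, latVox) / 2
  halfSpan <- sqrt((max(zpos))^2 + (max(lpos))^2) / 2
  t <- seq(-halfSpan, halfSpan, by = step)
  pz <- zc + t * dirz
  pl <- lc + t * dirl
  keep <- pz >= 0 & pz <= max(zpos) & pl >= 0 & pl <= max(lpos)
  t <- t[keep]; pz <- pz[keep]; pl <- pl[keep]
  val <- bilinearSample(sec, pz / zVox + 1, pl / latVox + 1)
  list(position = t - min(t), intensity = val,
    angleDeg = abs(rad2deg(ang)))
}

bilinearSample <- function(m, ri, ci) {
  r0 <- pmax(1L, pmin(nrow(m) - 1L, floor(ri)))
  c0 <- pmax(1L, pmin(ncol(m) - 1L, floor(ci)))
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Fit a Gaussian to an intensity profile and return its FWHM
#'
#' Least-squares fit of \code{offset + amplitude * exp(-(x - center)^2 /
#' (2 sigma^2))}; FWHM = \code{2 sqrt(2 ln 2) sigma}. Initialization:
#' center at the argmax, sigma from the profile's second moment, offset at
#' the profile minimum.
#'
#' @param intensity profile values (>= 7 samples; peak not at an edge).
#' @param position sample positions in um, or a scalar spacing.
#' @return list with \code{fwhm} (um), \code{sigma}, \code{center},
#'   \code{amplitude}, \code{offset}, \code{r2}.
#' @examples
#' x <- seq(-5, 5, by = 0.25)
#' fitGaussianFwhm(exp(-x^2 / 2), x)$fwhm  # ~2.3548
#' @export
fitGaussianFwhm <- function(intensity, position) {
  if (length(position) == 1L)
    position <- (seq_along(intensity) - 1) * position
  y <- as.numeric(intensity); x <- as.numeric(position)
  if (length(y) < 7L) stop("at least 7 samples are required for a fit")
  pk <- which.max(y)
  if (pk == 1L || pk == length(y))
    stop("profile peak lies at an edge; cannot fit")
  off0 <- min(y)
  amp0 <- max(y) - off0
  w <- pmax(y - off0, 0)
  mu0 <- sum(x * w) / sum(w)
  sd0 <- sqrt(sum((x - mu0)^2 * w) / sum(w))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- diff(range(x)) / 6
  resfun <- function(p) y - (p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2)))
  fit <- minpack.lm::nls.lm(
    par = c(off = off0, amp = amp0, mu = x[pk], sg = sd0), fn = resfun,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!(fit$info %in% 1:4))
    stop("Gaussian fit failed to converge: ", fit$message,
      " (residual norm ", signif(sqrt(sum(fit$fvec^2)), 4), ")",
      call. = FALSE)
  cf <- fit$par
  res <- fit$fvec
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  sg <- abs(unname(cf["sg"]))
  list(fwhm = FWHM_FACTOR * sg, sigma = sg, center = unname(cf["mu"]),
    amplitude = unname(cf["amp"]), offset = unname(cf["off"]), r2 = r2)
}

#' Characterize a bead volume: lateral and axial FWHMs
#'
#' Composes [extractProfiles()] and [fitGaussianFwhm()]. The axial FWHM is
#' the arithmetic mean of the values fitted on the XZ and YZ sections.
#'
#' @param vol a [BeadVolume-class].
#' @return list with \code{lateralX}, \code{lateralY}, \code{axial},
#'   \code{axialXZ}, \code{axialYZ} (um) and \code{fitR2}, a named numeric
#'   of per-axis goodness of fit.
#' @export
characterizeBead <- function(vol) {
  pr <- extractProfiles(vol)
  fx <- fitGaussianFwhm(pr$x$intensity, pr$x$position)
  fy <- fitGaussianFwhm(pr$y$intensity, pr$y$position)
  fxz <- fitGaussianFwhm(pr$axialXZ$intensity, pr$axialXZ$position)
  fyz <- fitGaussianFwhm(pr$axialYZ$intensity, pr$axialYZ$position)
  list(
    lateralX = fx$fwhm, lateralY = fy$fwhm,
    axial = (fxz$fwhm + fyz$fwhm) / 2,
    axialXZ = fxz$fwhm, axialYZ = fyz$fwhm,
    fitR2 = c(x = fx$r2, y = fy$r2, xz = fxz$r2, yz = fyz$r2)
  )
}
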