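# Per-trace transformations: percentile dF/F baseline, zero-phase Gaussian
# filtering of deconvolved events, peak detection, frame-skip
# down-sampling, clock resampling, and lever-movement masking.

#' Compute dF/F against a whole-series percentile baseline
#'
#' The baseline F0 of each unit is the given percentile (default the 8th)
#' of its entire acquired time series; the trace becomes (F - F0) / F0.
#' Units whose baseline is not strictly positive cannot be normalized;
#' they are excluded with a warning and listed in the \code{flagged}
#' attribute.
#'
#' @param raw a [TraceMatrix-class] of raw fluorescence.
#' @param baselinePercentile percentile (0-100) used for F0.
#' @return A [TraceMatrix-class] of dF/F with attribute \code{flagged},
#'   the ids of excluded units.
#' @export
computeDFF <- function(raw, baselinePercentile = 8) {
  stopifnot(is(raw, "TraceMatrix"))
  v <- raw@values
  f0 <- apply(v, 1, stats::quantile, probs = baselinePercentile / 100,
    names = FALSE, type = 7)
  bad <- f0 <= 0
  if (any(bad))
    warning(sprintf("%d unit(s) with baseline <= 0 excluded: %s",
      sum(bad), paste(raw@unitIds[bad], collapse = ", ")))
  dff <- (v[!bad, , drop = FALSE] - f0[!bad]) / f0[!bad]
  out <- traceMatrix(dff, raw@frameRate, raw@frameTimestamps,
    raw@unitIds[!bad])
  attr(out, "flagged") <- raw@unitIds[bad]
  out
}

# Unit-sum Gaussian kernel truncated at +/- 4 sigma (in samples).
gaussianKernel <- function(sigmaSamples) {
  half <- max(1L, ceiling(4 * sigmaSamples))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigmaSamples^2))
  k / sum(k)
}

# Symmetric-kernel convolution with reflected edges; zero phase by
# construction (equivalent to forward-backward filtering for a symmetric
# FIR kernel).
convolveReflect <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  # mirror without repeating the edge sample
  left <- if (half > 0) x[pmin(n, (half + 1):2)] else numeric(0)
  right <- if (half > 0) x[pmax(1, (n - 1):(n - half))] else numeric(0)
  pad <- c(left, x, right)
  out <- stats::filter(pad, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Zero-phase Gaussian filtering of event trains
#'
#' Convolves each unit's events with a unit-sum Gaussian kernel of the
#' given standard deviation (100 ms for soma-soma correlations, 500 ms for
#' soma-axon). The kernel is symmetric and applied in a single pass with
#' reflected edges, so the filter introduces no lag and conserves total
#' mass away from the edges.
#'
#' @param ev an [EventMatrix-class] (or TraceMatrix).
#' @param sigmaS kernel standard deviation in seconds.
#' @return Filtered object of the same class.
#' @export
gaussianFilterZeroPhase <- function(ev, sigmaS = 0.1) {
  stopifnot(is(ev, "TraceMatrix"), sigmaS > 0)
  sigmaSamples <- sigmaS * ev@frameRate
  if (sigmaSamples < 0.5) {
    warning("sigma is shorter than half a frame; filter is near-identity")
    sigmaSamples <- max(sigmaSamples, 1e-3)
  }
  k <- gaussianKernel(sigmaSamples)
  v <- t(apply(ev@values, 1, convolveReflect, k = k))
  if (nrow(ev@values) == 1L) v <- matrix(v, nrow = 1)
  out <- ev
  out@values <- v
  out
}

#' Detect peak events on filtered event traces
#'
#' A peak is a strict local maximum (greater than both neighbors) whose
#' height exceeds \code{thresholdSd} times the per-unit standard deviation
#' of the filtered trace. Used with the rule that only units showing more
#' than \code{minPeaks} peaks over the analyzed period are retained for
#' pairwise analyses.
#'
#' @param evFiltered filtered [EventMatrix-class].
#' @param thresholdSd threshold in per-unit s.d. units.
#' @return list with \code{counts} (named integer) and \code{indices}
#'   (list of frame indices per unit).
#' @export
detectPeakEvents <- function(evFiltered, thresholdSd = 2) {
  stopifnot(is(evFiltered, "TraceMatrix"))
  v <- evFiltered@values
  if (ncol(v) < 3L) stop("at least 3 frames are required")
  idx <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    thr <- thresholdSd * stats::sd(x)
    n <- length(x)
    cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
    cand[x[cand] > thr]
  })
  names(idx) <- evFiltered@unitIds
  list(counts = vapply(idx, length, integer(1)), indices = idx)
}

#' Down-sample by skipping frames
#'
#' Keeps frames 1, 1+factor, 1+2*factor, ... (pure decimation, no
#' averaging or anti-alias filtering) and divides the frame rate by the
#' factor.
#'
#' @param x a [TraceMatrix-class] or [EventMatrix-class].
#' @param factor integer skip factor >= 1.
#' @return Same class on the decimated clock.
#' @export
downsampleBySkip <- function(x, factor) {
  stopifnot(is(x, "TraceMatrix"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  n <- ncol(x@values)
  if (factor > n) stop("factor exceeds the number of frames")
  keep <- seq(1L, n, by = factor)
  out <- x
  out@values <- x@values[, keep, drop = FALSE]
  out@frameRate <- x@frameRate / factor
  if (length(x@frameTimestamps))
    out@frameTimestamps <- x@frameTimestamps[keep]
  out
}

#' Resample traces onto a target acquisition clock
#'
#' Linear interpolation of every unit onto the given timestamps (the union
#' clock of two interleaved fields doubles the per-field rate: two fields
#' at 5.4 Hz give a 10.8 Hz resampled clock). Requests outside the source
#' time span are an error, not an extrapolation.
#'
#' @param x a [TraceMatrix-class] or [EventMatrix-class].
#' @param targetTimestamps strictly increasing times, s, within the span
#'   of \code{frameTimes(x)}.
#' @return Same class on the new clock; frame rate set to the mean target
#'   rate.
#' @export
resampleToClock <- function(x, targetTimestamps) {
  stopifnot(is(x, "TraceMatrix"))
  src <- frameTimes(x)
  tt <- as.numeric(targetTimestamps)
  if (min(tt) < min(src) - 1e-12 || max(tt) > max(src) + 1e-12)
    stop("target timestamps extend beyond the source span; extrapolation is not allowed")
  v <- t(apply(x@values, 1, function(row)
    stats::approx(src, row, xout = tt)$y))
  if (nrow(x@values) == 1L) v <- matrix(v, nrow = 1)
  out <- x
  out@values <- v
  out@frameTimestamps <- tt
  out@frameRate <- if (length(tt) > 1) 1 / mean(diff(tt)) else x@frameRate
  out
}

#' Interleaved dual-field acquisition clock
#'
#' Union clock of two fields imaged alternately at \code{perFieldRate} Hz
#' each, the second offset by half a per-field period.
#'
#' @param perFieldRate per-field rate, Hz.
#' @param duration total duration, s.
#' @return Sorted vector of acquisition times, s (effective rate
#'   \code{2 * perFieldRate}).
#' @export
dualFieldClock <- function(perFieldRate, duration) {
  per <- 1 / perFieldRate
  a <- seq(0, duration, by = per)
  b <- a + per / 2
  sort(c(a, b[b <= duration]))
}

#' Mask lever-movement periods out of a recording
#'
#' Drops every frame falling within any movement interval padded by
#' \code{padS} seconds on each side (the non-lever-moving concatenation on
#' which resting-state correlations are computed) and returns the kept
#' frames concatenated in order together with the index map.
#'
#' @param x a [TraceMatrix-class] or [EventMatrix-class].
#' @param leverMoveIntervals two-column matrix or data.frame of
#'   \code{(start_s, end_s)} movement intervals.
#' @param padS padding in seconds applied before and after each interval.
#' @return Same class restricted to quiet frames, with attribute
#'   \code{keptFrames}, the original frame indices retained.
#' @export
maskLeverPeriods <- function(x, leverMoveIntervals, padS = 1.0) {
  stopifnot(is(x, "TraceMatrix"))
  t <- frameTimes(x)
  keep <- rep(TRUE, length(t))
  if (length(leverMoveIntervals)) {
    iv <- as.matrix(leverMoveIntervals)
    if (ncol(iv) != 2L) stop("intervals must have two columns (start_s, end_s)")
    for (r in seq_len(nrow(iv))) {
      keep <- keep & !(t >= iv[r, 1] - padS & t <= iv[r, 2] + padS)
    }
  }
  if (!any(keep)) stop("masking removed every frame")
  out <- x
  out@values <- x@values[, keep, drop = FALSE]
  if (length(x@frameTimestamps)) out@frameTimestamps <- x@frameTimestamps[keep]
  # concatenated data keep the nominal rate; timestamps are dropped to
  # reflect that the kept frames are analyzed as a contiguous series
  out@frameTimestamps <- numeric(0)
  attr(out, "keptFrames") <- which(keep)
  out
}
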