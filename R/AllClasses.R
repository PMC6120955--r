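#' @import methods
NULL

#' Mirror-device configuration
#'
#' Geometry and timing constants of the rotating post-objective mirror pair:
#' the inter-mirror distance sets the radius of the observable annulus, the
#' mirror dimensions set the beam ellipticity, and the scan/rotation timings
#' set the achievable dual-field frame rate.
#'
#' @slot dMirrorMirror numeric(1). Distance between the two micromirrors, mm.
#' @slot mirrorWidth numeric(1). Mirror side perpendicular to the beam, mm.
#' @slot mirrorHeight numeric(1). Mirror height, mm.
#' @slot workingDistance numeric(1). Objective working distance, mm.
#' @slot fovSide numeric(1). Side of the square field of view, mm.
#' @slot scanTimeMs numeric(1). Time to scan one frame, ms.
#' @slot rotationTimeMs named numeric. Rotation durations in ms, names are
#'   rotation angles in degrees (e.g. \code{c("60" = 43, "180" = 80)}).
#' @slot dMirrorCoverglass numeric(1). Mirror-holder-to-coverglass gap, mm.
#' @slot imagingDepth numeric(1). Imaging depth below the window, mm.
#'
#' @seealso [deviceConfig()] for the user-facing constructor.
#' @exportClass DeviceConfig
setClass("DeviceConfig",
  representation(
    dMirrorMirror = "numeric",
    mirrorWidth = "numeric",
    mirrorHeight = "numeric",
    workingDistance = "numeric",
    fovSide = "numeric",
    scanTimeMs = "numeric",
    rotationTimeMs = "numeric",
    dMirrorCoverglass = "numeric",
    imagingDepth = "numeric"
  ),
  prototype(
    dMirrorMirror = 2.5, mirrorWidth = 4.0, mirrorHeight = 2.5,
    workingDistance = 8.0, fovSide = 1.0, scanTimeMs = 33.3,
    rotationTimeMs = c("60" = 43, "180" = 80),
    dMirrorCoverglass = 1.0, imagingDepth = 0.2
  )
)

setValidity("DeviceConfig", function(object) {
  msg <- character(0)
  lens <- c(
    dMirrorMirror = object@dMirrorMirror, mirrorWidth = object@mirrorWidth,
    mirrorHeight = object@mirrorHeight, workingDistance = object@workingDistance,
    fovSide = object@fovSide, scanTimeMs = object@scanTimeMs,
    dMirrorCoverglass = object@dMirrorCoverglass, imagingDepth = object@imagingDepth
  )
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths and durations must be strictly positive")
  if (object@fovSide >= object@dMirrorMirror)
    msg <- c(msg, "fovSide must be smaller than dMirrorMirror")
  rt <- object@rotationTimeMs
  if (length(rt)) {
    if (is.null(names(rt)) || anyNA(suppressWarnings(as.numeric(names(rt)))))
      msg <- c(msg, "rotationTimeMs must be named by angle in degrees")
    else {
      ang <- as.numeric(names(rt))
      o <- order(ang)
      if (any(rt[o] < 0)) msg <- c(msg, "rotation times must be nonnegative")
      if (is.unsorted(rt[o])) msg <- c(msg, "rotationTimeMs must be nondecreasing in angle")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DeviceConfig
#'
#' Defaults correspond to the device the pipeline was designed around:
#' 2.5 mm inter-mirror distance, 4.0 x 2.5 mm mirrors, an 8 mm working
#' distance objective, a 1 mm square FOV, 33.3 ms per 512 x 512 frame
#' (8 kHz resonant scanner) and measured rotation times of 43 ms (60 deg)
#' and 80 ms (180 deg).
#'
#' @param dMirrorMirror inter-mirror distance, mm.
#' @param mirrorWidth,mirrorHeight mirror dimensions, mm.
#' @param workingDistance objective working distance, mm.
#' @param fovSide square FOV side, mm.
#' @param scanTimeMs frame scan duration, ms.
#' @param rotationTimeMs named numeric, rotation durations (ms) by angle (deg).
#' @param dMirrorCoverglass mirror-to-coverglass distance, mm.
#' @param imagingDepth imaging depth, mm.
#' @return A [DeviceConfig-class] object.
#' @examples
#' cfg <- deviceConfig()
#' centerDistance(cfg, 180)
#' @export
deviceConfig <- function(dMirrorMirror = 2.5, mirrorWidth = 4.0,
                         mirrorHeight = 2.5, workingDistance = 8.0,
                         fovSide = 1.0, scanTimeMs = 33.3,
                         rotationTimeMs = c("60" = 43, "180" = 80),
                         dMirrorCoverglass = 1.0, imagingDepth = 0.2) {
  new("DeviceConfig",
    dMirrorMirror = dMirrorMirror, mirrorWidth = mirrorWidth,
    mirrorHeight = mirrorHeight, workingDistance = workingDistance,
    fovSide = fovSide, scanTimeMs = scanTimeMs,
    rotationTimeMs = rotationTimeMs,
    dMirrorCoverglass = dMirrorCoverglass, imagingDepth = imagingDepth
  )
}

setMethod("show", "DeviceConfig", function(object) {
  cat("DeviceConfig\n")
  cat("  d(mirror-mirror):", object@dMirrorMirror, "mm\n")
  cat("  mirrors:", object@mirrorWidth, "x", object@mirrorHeight, "mm\n")
  cat("  FOV side:", object@fovSide, "mm; scan:", object@scanTimeMs, "ms\n")
  cat("  rotation times:", paste0(names(object@rotationTimeMs), "deg=",
    object@rotationTimeMs, "ms", collapse = ", "), "\n")
})

#' Trace matrix: units x frames time series
#'
#' Container for fluorescence or dF/F traces of a set of units (somata,
#' boutons, or pixels) on a common acquisition clock. When two interleaved
#' fields share one clock, per-frame timestamps carry the true acquisition
#' times.
#'
#' @slot values numeric matrix, units x frames.
#' @slot frameRate numeric(1), Hz.
#' @slot frameTimestamps numeric, per-frame acquisition times in seconds
#'   (length 0 when the clock is uniform at \code{frameRate}).
#' @slot unitIds character, one id per row.
#' @exportClass TraceMatrix
setClass("TraceMatrix",
  representation(
    values = "matrix",
    frameRate = "numeric",
    frameTimestamps = "numeric",
    unitIds = "character"
  )
)

setValidity("TraceMatrix", function(object) {
  msg <- character(0)
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  ts <- object@frameTimestamps
  if (length(ts)) {
    if (length(ts) != ncol(object@values))
      msg <- c(msg, "frameTimestamps length must equal the number of frames")
    if (any(diff(ts) <= 0))
      msg <- c(msg, "frameTimestamps must be strictly increasing")
  }
  if (length(object@unitIds) != nrow(object@values))
    msg <- c(msg, "unitIds length must equal the number of rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn TraceMatrix-class constructor.
#' @param values units x frames matrix.
#' @param frameRate acquisition rate, Hz.
#' @param frameTimestamps optional per-frame times, s.
#' @param unitIds optional row ids (default \code{u1, u2, ...}).
#' @export
traceMatrix <- function(values, frameRate, frameTimestamps = numeric(0),
                        unitIds = NULL) {
  values <- as.matrix(values)
  if (is.null(unitIds)) {
    unitIds <- if (!is.null(rownames(values))) rownames(values)
      else paste0("u", seq_len(nrow(values)))
  }
  new("TraceMatrix", values = values, frameRate = frameRate,
    frameTimestamps = as.numeric(frameTimestamps), unitIds = as.character(unitIds))
}

#' Event matrix: nonnegative deconvolved spike-event amplitudes
#'
#' Same layout as [TraceMatrix-class] but restricted to nonnegative values;
#' rows hold the deconvolved calcium-transient amplitudes ("inferred spike
#' events") that serve as the pipeline's primary activity signal.
#'
#' @exportClass EventMatrix
setClass("EventMatrix", contains = "TraceMatrix")

setValidity("EventMatrix", function(object) {
  if (any(object@values < 0, na.rm = TRUE))
    "event amplitudes must be nonnegative" else TRUE
})

#' @describeIn EventMatrix-class constructor.
#' @param values,frameRate,frameTimestamps,unitIds as in [traceMatrix()].
#' @export
eventMatrix <- function(values, frameRate, frameTimestamps = numeric(0),
                        unitIds = NULL) {
  tm <- traceMatrix(values, frameRate, frameTimestamps, unitIds)
  new("EventMatrix", tm)
}

setMethod("show", "TraceMatrix", function(object) {
  cat(class(object), "with", nrow(object@values), "units x",
    ncol(object@values), "frames @", object@frameRate, "Hz\n")
})

#' Bead image volume
#'
#' A z-stack of a (sub-diffraction) fluorescent bead, voxel-indexed
#' \code{[z, y, x]}, used for point-spread-function characterization.
#'
#' @slot intensity 3-D numeric array, \code{[z, y, x]}, nonnegative.
#' @slot voxelSize named numeric \code{c(x=, y=, z=)}, micrometres per voxel.
#' @slot framesPerPlane integer(1). Repeats averaged per focal plane.
#' @exportClass BeadVolume
setClass("BeadVolume",
  representation(intensity = "array", voxelSize = "numeric",
    framesPerPlane = "integer"),
  prototype(framesPerPlane = 1L)
)

setValidity("BeadVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@intensity)) != 3L)
    msg <- c(msg, "intensity must be a 3-D array [z, y, x]")
  vs <- object@voxelSize
  if (length(vs) != 3L || is.null(names(vs)) ||
      !all(c("x", "y", "z") %in% names(vs)) || any(vs <= 0))
    msg <- c(msg, "voxelSize must be positive and named x, y, z")
  if (length(msg)) msg else TRUE
})

#' @describeIn BeadVolume-class constructor.
#' @param intensity 3-D array \code{[z, y, x]}.
#' @param voxelSize named numeric \code{c(x=, y=, z=)} in um.
#' @param framesPerPlane repeats averaged per plane.
#' @export
beadVolume <- function(intensity, voxelSize = c(x = 0.249, y = 0.249, z = 0.5),
                       framesPerPlane = 1L) {
  new("BeadVolume", intensity = intensity,
    voxelSize = voxelSize[c("x", "y", "z")],
    framesPerPlane = as.integer(framesPerPlane))
}

setMethod("show", "BeadVolume", function(object) {
  d <- dim(object@intensity)
  cat("BeadVolume", d[3], "x", d[2], "x", d[1], "(x,y,z) voxels @",
    paste(object@voxelSize, collapse = " x "), "um\n")
})

#' ROI spatial footprint
#'
#' One extracted spatial component: a patch of nonnegative pixel weights
#' plus its offset in the field, the unit centroid in micrometres, and
#' area/field labels.
#'
#' @slot weights numeric matrix (rows = y, cols = x), nonnegative.
#' @slot offset numeric \code{c(x=, y=)}, pixel offset of the patch within
#'   the field (0-based).
#' @slot centroid numeric \code{c(x=, y=)}, micrometres in field coordinates.
#' @slot fieldId character(1).
#' @slot areaLabel character(1), e.g. "RFA", "MID", "CFA".
#' @exportClass RoiFootprint
setClass("RoiFootprint",
  representation(weights = "matrix", offset = "numeric", centroid = "numeric",
    fieldId = "character", areaLabel = "character"),
  prototype(offset = c(x = 0, y = 0), fieldId = "f1", areaLabel = "NA")
)

setValidity("RoiFootprint", function(object) {
  msg <- character(0)
  if (!any(object@weights > 0)) msg <- c(msg, "footprint needs a positive weight")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn RoiFootprint-class constructor.
#' @param weights weight patch (y rows, x cols).
#' @param offset patch offset \code{c(x=, y=)} in pixels.
#' @param centroid unit centroid \code{c(x=, y=)} in um.
#' @param fieldId,areaLabel labels.
#' @export
roiFootprint <- function(weights, offset = c(x = 0, y = 0),
                         centroid = NULL, fieldId = "f1", areaLabel = "NA") {
  weights <- as.matrix(weights)
  if (is.null(centroid)) centroid <- c(x = NA_real_, y = NA_real_)
  new("RoiFootprint", weights = weights, offset = offset, centroid = centroid,
    fieldId = fieldId, areaLabel = areaLabel)
}

#' ROI set: footprints linked to activity rows
#'
#' @slot footprints list of [RoiFootprint-class], one per unit, ordered as
#'   the rows of the linked matrices.
#' @slot scale numeric(1), micrometres per pixel.
#' @slot traces [TraceMatrix-class] or NULL.
#' @slot events [EventMatrix-class] or NULL.
#' @exportClass RoiSet
setClass("RoiSet",
  representation(footprints = "list", scale = "numeric",
    traces = "ANY", events = "ANY"),
  prototype(traces = NULL, events = NULL)
)

setValidity("RoiSet", function(object) {
  msg <- character(0)
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  n <- length(object@footprints)
  for (tm in list(object@traces, object@events)) {
    if (!is.null(tm) && nrow(tm@values) != n)
      msg <- c(msg, "one activity row per footprint is required")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RoiSet-class constructor.
#' @param footprints list of [RoiFootprint-class].
#' @param scale um per pixel.
#' @param traces,events optional linked matrices.
#' @export
roiSet <- function(footprints, scale, traces = NULL, events = NULL) {
  new("RoiSet", footprints = footprints, scale = scale,
    traces = traces, events = events)
}

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet with", length(object@footprints), "footprints @",
    object@scale, "um/px\n")
})

#' @describeIn RoiSet-class number of ROIs.
#' @param x a RoiSet.
#' @export
setMethod("length", "RoiSet", function(x) length(x@footprints))

#' Behavior log of the sound-cued lever-pull task
#'
#' @slot leverPosition numeric, lever position in mm sampled at \code{rate}.
#' @slot rate numeric(1), Hz.
#' @slot cueTimes numeric, tone onsets, s.
#' @slot rewardTimes numeric, reward deliveries, s.
#' @exportClass BehaviorLog
setClass("BehaviorLog",
  representation(leverPosition = "numeric", rate = "numeric",
    cueTimes = "numeric", rewardTimes = "numeric")
)

setValidity("BehaviorLog", function(object) {
  msg <- character(0)
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  dur <- length(object@leverPosition) / object@rate
  ev <- c(object@cueTimes, object@rewardTimes)
  if (length(ev) && (any(ev < 0) || any(ev > dur)))
    msg <- c(msg, "event times must lie within the recording")
  if (length(msg)) msg else TRUE
})

#' @describeIn BehaviorLog-class constructor.
#' @param leverPosition lever trace, mm.
#' @param rate sampling rate, Hz.
#' @param cueTimes,rewardTimes event times, s.
#' @export
behaviorLog <- function(leverPosition, rate, cueTimes = numeric(0),
                        rewardTimes = numeric(0)) {
  new("BehaviorLog", leverPosition = as.numeric(leverPosition), rate = rate,
    cueTimes = as.numeric(cueTimes), rewardTimes = as.numeric(rewardTimes))
}

setMethod("show", "BehaviorLog", function(object) {
  cat("BehaviorLog:", round(length(object@leverPosition) / object@rate, 1),
    "s @", object@rate, "Hz;", length(object@cueTimes), "cues,",
    length(object@rewardTimes), "rewards\n")
})

#' Per-area trial population-activity matrix
#'
#' Cells x trials matrix of time-averaged z-scored inferred spike events
#' over the movement-related window; the column vectors are the trial
#' population vectors fed to the clustering.
#'
#' @slot area character(1).
#' @slot values numeric matrix, cells x trials, no missing entries.
#' @slot trialIds integer, aligned across areas of a session.
#' @slot cellIds character.
#' @exportClass PopulationMatrix
setClass("PopulationMatrix",
  representation(area = "character", values = "matrix",
    trialIds = "integer", cellIds = "character")
)

setValidity("PopulationMatrix", function(object) {
  msg <- character(0)
  if (anyNA(object@values)) msg <- c(msg, "no undefined entries allowed")
  if (length(object@trialIds) != ncol(object@values))
    msg <- c(msg, "one trial id per column required")
  if (length(object@cellIds) != nrow(object@values))
    msg <- c(msg, "one cell id per row required")
  if (length(msg)) msg else TRUE
})

#' @describeIn PopulationMatrix-class constructor.
#' @param area area label.
#' @param values cells x trials matrix.
#' @param trialIds,cellIds identifiers.
#' @export
populationMatrix <- function(area, values, trialIds = seq_len(ncol(values)),
                             cellIds = paste0("c", seq_len(nrow(values)))) {
  new("PopulationMatrix", area = area, values = as.matrix(values),
    trialIds = as.integer(trialIds), cellIds = as.character(cellIds))
}

setMethod("show", "PopulationMatrix", function(object) {
  cat("PopulationMatrix [", object@area, "]:", nrow(object@values),
    "cells x", ncol(object@values), "trials\n")
})

#' Affinity-propagation clustering result
#'
#' @slot labels integer, cluster label (1..k) per point.
#' @slot exemplars integer, exemplar point index per cluster.
#' @slot k integer(1).
#' @slot similarity character(1), "cc" or "neg_sq_euclidean".
#' @slot preference numeric(1), the preference actually applied.
#' @slot damping numeric(1).
#' @slot iterations integer(1), message-passing iterations run.
#' @slot converged logical(1).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(labels = "integer", exemplars = "integer", k = "integer",
    similarity = "character", preference = "numeric", damping = "numeric",
    iterations = "integer", converged = "logical")
)

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@exemplars) != object@k)
    msg <- c(msg, "one exemplar per cluster required")
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must map into 1..k")
  ex <- object@exemplars
  if (length(ex) && !all(object@labels[ex] == seq_along(ex)))
    msg <- c(msg, "exemplars must label themselves")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "clusters over", length(object@labels),
    "points;", if (object@converged) "converged" else "NOT converged",
    "after", object@iterations, "iterations\n")
})

#' @describeIn ClusterResult-class number of clusters.
#' @param object a ClusterResult.
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname ClusterResult-class
#' @export
setMethod("nClusters", "ClusterResult", function(object) object@k)

#' @describeIn ClusterResult-class per-point cluster labels.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

# ---- shared accessors -------------------------------------------------------

#' Matrix of values inside a container
#' @param object a TraceMatrix, EventMatrix or PopulationMatrix.
#' @return the underlying numeric matrix.
#' @export
setGeneric("activityValues", function(object) standardGeneric("activityValues"))

#' @rdname activityValues
#' @export
setMethod("activityValues", "TraceMatrix", function(object) object@values)

#' @rdname activityValues
#' @export
setMethod("activityValues", "PopulationMatrix", function(object) object@values)

#' Acquisition frame rate
#' @param object a TraceMatrix or EventMatrix.
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname frameRate
#' @export
setMethod("frameRate", "TraceMatrix", function(object) object@frameRate)

#' Frame timestamps (seconds); computed from the rate when not stored
#' @param object a TraceMatrix or EventMatrix.
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "TraceMatrix", function(object) {
  if (length(object@frameTimestamps)) object@frameTimestamps
  else (seq_len(ncol(object@values)) - 1) / object@frameRate
})

#' Unit identifiers
#' @param object a TraceMatrix or EventMatrix.
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))

#' @rdname unitIds
#' @export
setMethod("unitIds", "TraceMatrix", function(object) object@unitIds)
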