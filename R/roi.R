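# Somatic ROI selection: footprint shape metrics (area, moment-ellipse
# eccentricity) and the size/eccentricity keep rule that removes extracted
# apical dendrites from L2/3 planes.

#' Shape metrics of a spatial footprint
#'
#' Area is the count of pixels whose weight exceeds a fraction of the
#' footprint's maximum (extracted footprints are soft), scaled by the
#' pixel size squared. Eccentricity is that of the ellipse with the same
#' second central moments as the weight distribution; a weighted variant
#' (default) and a binary-mask variant are available.
#'
#' @param roi a [RoiFootprint-class].
#' @param scale micrometres per pixel.
#' @param supportFraction pixels with weight above this fraction of the
#'   maximum count towards the area (default 0.1).
#' @param weighted logical; use weights (TRUE) or the binary support mask
#'   (FALSE) for the moments.
#' @return list with \code{area} (um^2) and \code{eccentricity} in [0, 1).
#' @export
footprintShapeMetrics <- function(roi, scale, supportFraction = 0.1,
                                  weighted = TRUE) {
  stopifnot(is(roi, "RoiFootprint"), scale > 0)
  w <- roi@weights
  mx <- max(w)
  if (mx <= 0) stop("footprint has empty support")
  support <- w > supportFraction * mx
  area <- sum(support) * scale^2
  m <- if (weighted) w * support else support * 1.0
  tot <- sum(m)
  ri <- row(m); ci <- col(m)
  rc <- sum(ri * m) / tot
  cc <- sum(ci * m) / tot
  mrr <- sum((ri - rc)^2 * m) / tot
  mcc <- sum((ci - cc)^2 * m) / tot
  mrc <- sum((ri - rc) * (ci - cc) * m) / tot
  # eigenvalues of the 2x2 second-moment matrix
  tr <- mrr + mcc
  disc <- sqrt(max(0, (mrr - mcc)^2 + 4 * mrc^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(area = area, eccentricity = ecc)
}

#' Select somatic components by size and eccentricity
#'
#' Keeps ROIs with area strictly greater than \code{minArea} AND
#' eccentricity strictly greater than \code{minEcc} (both comparators as
#' printed; the boundary is excluded). The rejection log records which
#' criterion failed for every dropped ROI.
#'
#' @param set a [RoiSet-class].
#' @param minArea minimum area, um^2.
#' @param minEcc minimum eccentricity.
#' @param comparator comparison for both rules: \code{">"} (default) or
#'   \code{">="}.
#' @param supportFraction passed to [footprintShapeMetrics()].
#' @return list with \code{set}, the filtered [RoiSet-class], and
#'   \code{rejections}, a data.frame (index, area, eccentricity, reason).
#' @export
selectSomaticComponents <- function(set, minArea = 50, minEcc = 0.5,
                                    comparator = c(">", ">="),
                                    supportFraction = 0.1) {
  stopifnot(is(set, "RoiSet"))
  comparator <- match.arg(comparator)
  cmp <- if (comparator == ">") `>` else `>=`
  n <- length(set@footprints)
  if (n == 0L)
    return(list(set = set, rejections = data.frame(index = integer(0),
      area = numeric(0), eccentricity = numeric(0), reason = character(0))))
  metrics <- lapply(set@footprints, footprintShapeMetrics,
    scale = set@scale, supportFraction = supportFraction)
  area <- vapply(metrics, `[[`, numeric(1), "area")
  ecc <- vapply(metrics, `[[`, numeric(1), "eccentricity")
  okA <- cmp(area, minArea)
  okE <- cmp(ecc, minEcc)
  keep <- okA & okE
  reason <- ifelse(!okA & !okE, "area+eccentricity",
    ifelse(!okA, "area", ifelse(!okE, "eccentricity", "")))
  rejections <- data.frame(index = which(!keep), area = area[!keep],
    eccentricity = ecc[!keep], reason = reason[!keep])
  filtered <- roiSet(
    footprints = set@footprints[keep],
    scale = set@scale,
    traces = subsetUnits(set@traces, keep),
    events = subsetUnits(set@events, keep)
  )
  list(set = filtered, rejections = rejections)
}

subsetUnits <- function(tm, keep) {
  if (is.null(tm)) return(NULL)
  out <- tm
  out@values <- tm@values[keep, , drop = FALSE]
  out@unitIds <- tm@unitIds[keep]
  out
}

#' Centroid coordinate table of a RoiSet
#'
#' @param set a [RoiSet-class].
#' @return data.frame with columns unit, x, y (um), fieldId, areaLabel.
#' @export
roiCentroids <- function(set) {
  stopifnot(is(set, "RoiSet"))
  do.call(rbind, lapply(seq_along(set@footprints), function(i) {
    fp <- set@footprints[[i]]
    data.frame(unit = i, x = fp@centroid["x"], y = fp@centroid["y"],
      fieldId = fp@fieldId, areaLabel = fp@areaLabel, row.names = NULL)
  }))
}
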