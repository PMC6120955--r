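# Pairwise correlation analyses: filtered-event correlation tables,
# distance-binned curves, inter-areal comparisons, correlation graphs,
# soma-axon bouton matching, and pixel-wise seed correlation maps.

#' Pairwise correlation table from Gaussian-filtered events
#'
#' Filters the events ([gaussianFilterZeroPhase()]; 100 ms sigma for
#' soma-soma pairs, 500 ms for soma-axon) and computes the Pearson
#' correlation of every unordered unit pair. Pairs involving a
#' zero-variance unit are undefined and dropped with a log entry.
#'
#' @param ev an [EventMatrix-class].
#' @param sigmaS filter standard deviation, s.
#' @param centroids optional data.frame (unit, x, y in um) for
#'   inter-centroid distances; from [roiCentroids()].
#' @param areaLabels optional character, one per unit.
#' @return data.frame with columns i, j, cc and, when available,
#'   distance (um), areaI, areaJ; attribute \code{dropped} lists
#'   zero-variance units.
#' @export
filteredEventCCMatrix <- function(ev, sigmaS = 0.1, centroids = NULL,
                                  areaLabels = NULL) {
  stopifnot(is(ev, "TraceMatrix"))
  if (nrow(ev@values) < 2L) stop("at least 2 units are required")
  if (ncol(ev@values) < 10L) stop("at least 10 frames are required")
  f <- gaussianFilterZeroPhase(ev, sigmaS)
  v <- f@values
  sds <- apply(v, 1, stats::sd)
  ok <- sds > 0
  C <- suppressWarnings(stats::cor(t(v[ok, , drop = FALSE])))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  okIdx <- which(ok)
  tab <- data.frame(
    i = okIdx[idx[, 1]], j = okIdx[idx[, 2]],
    cc = C[idx]
  )
  if (!is.null(centroids)) {
    xi <- centroids$x[match(tab$i, centroids$unit)]
    yi <- centroids$y[match(tab$i, centroids$unit)]
    xj <- centroids$x[match(tab$j, centroids$unit)]
    yj <- centroids$y[match(tab$j, centroids$unit)]
    tab$distance <- sqrt((xi - xj)^2 + (yi - yj)^2)
  }
  if (!is.null(areaLabels)) {
    tab$areaI <- areaLabels[tab$i]
    tab$areaJ <- areaLabels[tab$j]
  }
  attr(tab, "dropped") <- which(!ok)
  tab
}

#' Distance-binned pairwise correlation curve
#'
#' Groups pairs into fixed-width distance bins ([0, 250), [250, 500), ...
#' by default) and reports the mean and s.e.m. of the correlations per
#' bin. Empty bins are reported as missing, never as zero.
#'
#' @param tab a correlation table with \code{cc} and \code{distance}.
#' @param binUm bin width in um.
#' @return data.frame: binStart, binEnd, n, meanCC, semCC (NA when empty).
#' @export
distanceBinnedCC <- function(tab, binUm = 250) {
  if (is.null(tab$distance)) stop("correlation table has no distances")
  maxd <- max(tab$distance)
  starts <- seq(0, maxd, by = binUm)
  bin <- findInterval(tab$distance, starts)
  out <- data.frame(binStart = starts, binEnd = starts + binUm)
  out$n <- vapply(seq_along(starts), function(b) sum(bin == b), integer(1))
  out$meanCC <- vapply(seq_along(starts), function(b) {
    x <- tab$cc[bin == b]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  out$semCC <- vapply(seq_along(starts), function(b) {
    x <- tab$cc[bin == b]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  out
}

#' Assign cortical areas from an axis coordinate
#'
#' @param axisMm numeric, per-unit coordinate along the rostro-caudal axis
#'   in mm.
#' @param ranges named list of \code{c(lo, hi)} per area; defaults to
#'   RFA 1.5-2.5, MID 0.3-1.5, CFA -0.5-0.3 mm.
#' @return character vector of area labels (NA outside every range).
#' @export
assignAreas <- function(axisMm,
                        ranges = list(RFA = c(1.5, 2.5), MID = c(0.3, 1.5),
                                      CFA = c(-0.5, 0.3))) {
  out <- rep(NA_character_, length(axisMm))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    hit <- axisMm >= r[1] & axisMm < r[2] & is.na(out)
    out[hit] <- nm
  }
  out
}

#' Inter-areal correlation comparison
#'
#' Groups pairs by the areas of their two members (RFA-CFA, RFA-MID,
#' CFA-MID) and compares groups with two-sided Wilcoxon rank-sum tests.
#' Groups with fewer than 2 pairs are skipped.
#'
#' @param tab correlation table with \code{cc}, \code{areaI}, \code{areaJ}.
#' @return list with \code{groups} (data.frame: group, n, meanCC) and
#'   \code{tests} (data.frame: groupA, groupB, p).
#' @export
interAreaCCCompare <- function(tab) {
  if (is.null(tab$areaI)) stop("correlation table has no area labels")
  key <- apply(cbind(tab$areaI, tab$areaJ), 1, function(p)
    paste(sort(p), collapse = "-"))
  keep <- !is.na(tab$areaI) & !is.na(tab$areaJ) & tab$areaI != tab$areaJ
  key <- key[keep]
  cc <- tab$cc[keep]
  groups <- split(cc, key)
  gdf <- data.frame(group = names(groups),
    n = vapply(groups, length, integer(1)),
    meanCC = vapply(groups, mean, numeric(1)), row.names = NULL)
  nm <- names(groups)
  tests <- NULL
  if (length(nm) >= 2) {
    combs <- utils::combn(nm, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(c2) {
      a <- groups[[combs[1, c2]]]; b <- groups[[combs[2, c2]]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      data.frame(groupA = combs[1, c2], groupB = combs[2, c2],
        p = stats::wilcox.test(a, b)$p.value)
    }))
  }
  list(groups = gdf, tests = tests)
}

#' Threshold correlation graph
#'
#' Edges connect unit pairs whose correlation exceeds the threshold
#' (default 0.45).
#'
#' @param tab correlation table.
#' @param threshold edge threshold on cc.
#' @return data.frame of edges (i, j, cc) plus centroid columns when the
#'   input table has them.
#' @export
correlationGraph <- function(tab, threshold = 0.45) {
  tab[tab$cc > threshold, , drop = FALSE]
}

#' Match axonal boutons to candidate parent somata by correlation
#'
#' Events of both sets are Gaussian-filtered (default 500 ms sigma), units
#' with too few peak events are discarded (retention requires strictly
#' more than \code{minPeaks} peaks at the 2 s.d. peak threshold), and
#' every retained soma is correlated against every retained bouton. For
#' each soma the bouton CC distribution yields its mean, s.d., the
#' descending top-k list, and a z-score per bouton
#' ((cc - mean) / s.d.); candidate matches are boutons whose CC exceeds
#' \code{matchCC} or, when \code{matchZ} is given, whose z-score exceeds
#' it.
#'
#' @param somata,boutons [EventMatrix-class] objects on a common clock.
#' @param sigmaS filter sigma, s.
#' @param minPeaks retention threshold (exclusive) on peak-event counts.
#' @param topK length of the per-soma top list.
#' @param matchCC absolute CC criterion for a match.
#' @param matchZ optional z-score criterion; overrides \code{matchCC}.
#' @param thresholdSd peak threshold, s.d. units.
#' @return list with \code{cc} (soma x bouton matrix), \code{perSoma}
#'   (list with mean, sd, topK indices and values, z), \code{matches}
#'   (data.frame soma, bouton, cc, z), \code{retainedSomata},
#'   \code{retainedBoutons}.
#' @export
somaAxonMatch <- function(somata, boutons, sigmaS = 0.5, minPeaks = 10,
                          topK = 15, matchCC = 0.6, matchZ = NULL,
                          thresholdSd = 2) {
  stopifnot(is(somata, "TraceMatrix"), is(boutons, "TraceMatrix"))
  fs <- gaussianFilterZeroPhase(somata, sigmaS)
  fb <- gaussianFilterZeroPhase(boutons, sigmaS)
  keepS <- detectPeakEvents(fs, thresholdSd)$counts > minPeaks
  keepB <- detectPeakEvents(fb, thresholdSd)$counts > minPeaks
  if (!any(keepS) || !any(keepB))
    stop("no units survive the >", minPeaks, " peak-event filter")
  vs <- fs@values[keepS, , drop = FALSE]
  vb <- fb@values[keepB, , drop = FALSE]
  sdS <- apply(vs, 1, stats::sd)
  sdB <- apply(vb, 1, stats::sd)
  if (any(sdS == 0) || any(sdB == 0)) {
    keep2S <- sdS > 0; keep2B <- sdB > 0
    vs <- vs[keep2S, , drop = FALSE]; vb <- vb[keep2B, , drop = FALSE]
    keepS[keepS] <- keep2S; keepB[keepB] <- keep2B
  }
  cc <- stats::cor(t(vs), t(vb))
  rownames(cc) <- fs@unitIds[keepS]
  colnames(cc) <- fb@unitIds[keepB]
  perSoma <- lapply(seq_len(nrow(cc)), function(i) {
    x <- cc[i, ]
    mu <- mean(x); s <- stats::sd(x)
    o <- order(x, decreasing = TRUE)
    k <- min(topK, length(x))
    list(mean = mu, sd = s,
      topK = data.frame(bouton = o[seq_len(k)], cc = x[o[seq_len(k)]]),
      z = (x - mu) / s)
  })
  names(perSoma) <- rownames(cc)
  matchRows <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
    z <- perSoma[[i]]$z
    hit <- if (is.null(matchZ)) cc[i, ] > matchCC else z > matchZ
    if (!any(hit)) return(NULL)
    data.frame(soma = i, bouton = which(hit), cc = cc[i, hit], z = z[hit],
      row.names = NULL)
  }))
  if (is.null(matchRows))
    matchRows <- data.frame(soma = integer(0), bouton = integer(0),
      cc = numeric(0), z = numeric(0))
  list(cc = cc, perSoma = perSoma, matches = matchRows,
    retainedSomata = which(keepS), retainedBoutons = which(keepB))
}

#' z-score of a correlation against a CC distribution
#'
#' @param cc correlation value.
#' @param distMean,distSd mean and s.d. of the reference CC distribution.
#' @return \code{(cc - distMean) / distSd}.
#' @examples
#' ccDistributionZ(0.78, 0, 0.12)  # 6.5
#' @export
ccDistributionZ <- function(cc, distMean, distSd) (cc - distMean) / distSd

#' Pixel-wise seed correlation map
#'
#' Correlates the boxcar-smoothed trace of every movie pixel (default
#' 5-frame moving average) with the equally smoothed seed temporal
#' component, so a pixel carrying the seed itself maps to 1. Zero-variance
#' pixels map to NA.
#'
#' @param movie 3-D array \code{[frame, y, x]}.
#' @param seedTrace numeric, one value per frame.
#' @param movingAvg boxcar length in frames.
#' @return Correlation image (y x x matrix).
#' @export
pixelwiseCorrelationMap <- function(movie, seedTrace, movingAvg = 5) {
  d <- dim(movie)
  if (length(d) != 3L) stop("movie must be [frame, y, x]")
  if (d[1] != length(seedTrace))
    stop("seed trace and movie must share the same clock")
  k <- rep(1 / movingAvg, movingAvg)
  smoothPx <- function(x) {
    s <- stats::filter(x, k, sides = 2)
    as.numeric(s)
  }
  seed <- smoothPx(seedTrace)
  out <- matrix(NA_real_, d[2], d[3])
  flat <- matrix(movie, nrow = d[1])
  sm <- apply(flat, 2, smoothPx)
  keepT <- which(stats::complete.cases(sm))
  smv <- sm[keepT, , drop = FALSE]
  sv <- seed[keepT]
  sds <- apply(smv, 2, stats::sd)
  ccs <- rep(NA_real_, ncol(smv))
  pos <- sds > 0
  if (stats::sd(sv) > 0 && any(pos))
    ccs[pos] <- as.numeric(stats::cor(smv[, pos, drop = FALSE], sv))
  out[] <- ccs
  out
}
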