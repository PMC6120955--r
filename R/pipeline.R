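# Orchestration: configuration with the printed defaults for every stage
# parameter, and the end-to-end run from a (synthetic or loaded) session
# to a covariation report.

#' Analysis configuration with stage defaults
#'
#' Every parameter defaults to its standard value: 8th-percentile dF/F
#' baseline, 100 ms / 500 ms filter sigmas, 2 s.d. peak threshold with a
#' >10 peak retention rule, 50 um^2 / 0.5 ROI selection, movement window
#' -5..20 and rest window -25..-10 resampled frames, alpha 0.05, median
#' affinity-propagation preference with damping 0.9, and 1000 shuffles.
#'
#' @param ... overrides of the defaults.
#' @return list of class \code{analysisConfig}.
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    baselinePercentile = 8,
    somaSigmaS = 0.1,
    axonSigmaS = 0.5,
    peakThresholdSd = 2,
    minPeaks = 10,
    minArea = 50,
    minEcc = 0.5,
    moveWin = c(-5, 20),
    restWin = c(-25, -10),
    alpha = 0.05,
    rtRange = c(0.1, 0.5),
    leverWindow = c(-0.5, 2.0),
    behaviorLeverWindow = c(-0.43, 1.85),
    preference = "median",
    damping = 0.9,
    maxIter = 1000,
    stableIter = 100,
    similarity = "cc",
    nShuffles = 1000,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
    paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "analysisConfig"
  cfg
}

#' Read / write an analysis configuration as JSON
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param cfg an [analysisConfig()].
#' @param path JSON file path.
#' @return \code{readAnalysisConfig} returns the configuration.
#' @export
writeAnalysisConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysisConfig, raw)
}

#' Resample a session's events onto the dual-field clock
#'
#' Convenience for the standard path: native-clock events of both areas
#' linearly interpolated onto the union clock of the two interleaved
#' fields (10.8 Hz for 5.4 Hz per field).
#'
#' @param session output of [simulateDualAreaSession()] (or an equivalent
#'   list).
#' @return list with \code{rfa}, \code{cfa} ([EventMatrix-class] on the
#'   union clock).
#' @export
resampleSessionEvents <- function(session) {
  clock <- session$fieldClocks$union
  span <- range(frameTimes(session$rfa$events))
  clock <- clock[clock >= span[1] & clock <= span[2]]
  rs <- function(ev) {
    out <- resampleToClock(ev, clock)
    new("EventMatrix", traceMatrix(pmax(out@values, 0), out@frameRate,
      out@frameTimestamps, out@unitIds))
  }
  list(rfa = rs(session$rfa$events), cfa = rs(session$cfa$events))
}

#' Run the full dual-area covariation analysis
#'
#' Executes the standard stage order on a session: resample events to the
#' dual-field clock, classify movement-related neurons, build per-area
#' population matrices over the selected trials, cluster the source
#' area's trials by affinity propagation, and compute the cross-area
#' intra-cluster CC with its shuffle null plus the inter-cluster distance
#' agreement between areas. When \code{outDir} is given, the report, the
#' matrices and a provenance log (config, seed) are written there.
#'
#' @param session output of [simulateDualAreaSession()] or a compatible
#'   loaded bundle.
#' @param cfg an [analysisConfig()].
#' @param sourceArea which area's clustering drives the grouping.
#' @param outDir optional output directory.
#' @return list of class \code{covariationReport}: population matrices,
#'   cluster result, intra-cluster CC + null, inter-cluster distance
#'   matrices and their agreement, parameters used.
#' @export
runFullAnalysis <- function(session, cfg = analysisConfig(),
                            sourceArea = c("rfa", "cfa"), outDir = NULL) {
  sourceArea <- match.arg(sourceArea)
  res <- resampleSessionEvents(session)
  onsets <- session$onsets
  maskR <- classifyMovementRelated(res$rfa, onsets, cfg$moveWin, cfg$restWin,
    cfg$alpha)
  maskC <- classifyMovementRelated(res$cfa, onsets, cfg$moveWin, cfg$restWin,
    cfg$alpha)
  if (!any(maskR) || !any(maskC))
    stop("no movement-related neurons in at least one area")
  pmR <- buildPopulationMatrix(res$rfa, onsets, maskR, cfg$moveWin, "RFA")
  pmC <- buildPopulationMatrix(res$cfa, onsets, maskC, cfg$moveWin, "CFA")
  common <- intersect(pmR@trialIds, pmC@trialIds)
  subPm <- function(pm) populationMatrix(pm@area,
    pm@values[, match(common, pm@trialIds), drop = FALSE],
    trialIds = common, cellIds = pm@cellIds)
  pmR <- subPm(pmR); pmC <- subPm(pmC)
  src <- if (sourceArea == "rfa") pmR else pmC
  tgt <- if (sourceArea == "rfa") pmC else pmR
  S <- trialSimilarityMatrix(src, cfg$similarity)
  cl <- affinityPropagation(S, preference = cfg$preference,
    damping = cfg$damping, maxIter = cfg$maxIter,
    stableIter = cfg$stableIter)
  cross <- crossAreaIntraClusterCC(cl, tgt, nShuffles = cfg$nShuffles,
    seed = cfg$seed)
  agreement <- NULL
  if (cl@k >= 3) {
    dA <- interClusterDistances(src, cl, "cc")
    dB <- interClusterDistances(tgt, cl, "cc")
    agreement <- clusterDistanceAgreement(dA, dB)
    agreement$distSource <- dA
    agreement$distTarget <- dB
  }
  report <- list(
    populations = list(rfa = pmR, cfa = pmC),
    movementRelated = list(rfa = sum(maskR), cfa = sum(maskC)),
    clusters = cl,
    intraClusterCC = cross$intraCC,
    shuffleNullMean = cross$nullMean,
    shuffleNull = cross$nullValues,
    agreement = agreement,
    sourceArea = sourceArea,
    config = cfg
  )
  class(report) <- "covariationReport"
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAnalysisConfig(cfg, file.path(outDir, "config.json"))
    utils::write.csv(data.frame(trial = common, cluster = cl@labels),
      file.path(outDir, "clusters.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      intraClusterCC = cross$intraCC,
      shuffleNullMean = cross$nullMean,
      k = cl@k, converged = cl@converged,
      agreementR = if (is.null(agreement)) NA else agreement$r,
      movementRelated = report$movementRelated,
      seed = cfg$seed
    ), file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.covariationReport <- function(x, ...) {
  cat("Covariation report (source area:", toupper(x$sourceArea), ")\n")
  cat("  movement-related neurons:", x$movementRelated$rfa, "RFA /",
    x$movementRelated$cfa, "CFA\n")
  cat("  trials:", length(x$clusters@labels), "in", x$clusters@k, "clusters\n")
  cat("  cross-area intra-cluster CC:", round(x$intraClusterCC, 3),
    "(shuffle null mean:", round(x$shuffleNullMean, 3), ")\n")
  if (!is.null(x$agreement))
    cat("  inter-cluster distance agreement r:", round(x$agreement$r, 3), "\n")
  invisible(x)
}
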