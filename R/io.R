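# Plain-text and TIFF interfaces for traces, events, behavior logs and
# bead stacks.

#' Read / write trace or event tables as long-format CSV
#'
#' Long format: columns \code{unit, frame, value}; the frame rate and
#' optional timestamps travel in a JSON sidecar written next to the CSV.
#'
#' @param x a [TraceMatrix-class] or [EventMatrix-class].
#' @param path CSV path; the sidecar is \code{<path>.json}.
#' @return \code{readTraceCSV} returns the reconstructed object.
#' @export
writeTraceCSV <- function(x, path) {
  stopifnot(is(x, "TraceMatrix"))
  v <- x@values
  df <- data.frame(
    unit = rep(x@unitIds, times = ncol(v)),
    frame = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(
    frameRate = x@frameRate,
    frameTimestamps = x@frameTimestamps,
    class = class(x)[1]
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  units <- unique(df$unit)
  v <- matrix(NA_real_, length(units), max(df$frame))
  v[cbind(match(df$unit, units), df$frame)] <- df$value
  ts <- if (length(meta$frameTimestamps)) meta$frameTimestamps else numeric(0)
  if (identical(meta$class, "EventMatrix"))
    eventMatrix(v, meta$frameRate, ts, units)
  else traceMatrix(v, meta$frameRate, ts, units)
}

#' Read / write a behavior log as CSV
#'
#' The lever trace goes to \code{<path>} (columns time_s, lever_mm); cue
#' and reward events to \code{<path>.events.csv} (columns kind, time_s).
#'
#' @param log a [BehaviorLog-class].
#' @param path CSV path.
#' @return \code{readBehaviorCSV} returns the log.
#' @export
writeBehaviorCSV <- function(log, path) {
  stopifnot(is(log, "BehaviorLog"))
  t <- (seq_along(log@leverPosition) - 1) / log@rate
  utils::write.csv(data.frame(time_s = t, lever_mm = log@leverPosition),
    path, row.names = FALSE)
  ev <- rbind(
    data.frame(kind = "cue", time_s = log@cueTimes),
    data.frame(kind = "reward", time_s = log@rewardTimes)
  )
  utils::write.csv(ev, paste0(path, ".events.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehaviorCSV
#' @export
readBehaviorCSV <- function(path) {
  df <- utils::read.csv(path)
  rate <- 1 / stats::median(diff(df$time_s))
  ev <- utils::read.csv(paste0(path, ".events.csv"))
  behaviorLog(df$lever_mm, rate,
    cueTimes = ev$time_s[ev$kind == "cue"],
    rewardTimes = ev$time_s[ev$kind == "reward"])
}

#' Read a multi-page TIFF bead stack into a BeadVolume
#'
#' Plane order is z-major with repeats innermost; the repeat count and
#' voxel size come from a JSON sidecar (\code{<path>.json}, fields
#' \code{framesPerPlane} and \code{voxelSize}) or from the arguments.
#'
#' @param path TIFF path.
#' @param framesPerPlane,voxelUm used when no sidecar exists.
#' @return A [BeadVolume-class].
#' @export
readBeadTiff <- function(path, framesPerPlane = 5L,
                         voxelUm = c(x = 0.249, y = 0.249, z = 0.5)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    framesPerPlane <- meta$framesPerPlane
    voxelUm <- unlist(meta$voxelSize)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  averagePlaneRepeats(frames, framesPerPlane, voxelUm)
}

#' Write a correlation table, match table or FWHM table as CSV
#'
#' @param x a data.frame (or the list returned by [characterizeBead()],
#'   which is flattened to one row).
#' @param path CSV path.
#' @export
writeResultCSV <- function(x, path) {
  if (!is.data.frame(x)) {
    flat <- unlist(x)
    x <- as.data.frame(as.list(flat))
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
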