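# Sound-cued lever-pull task: trial detection (5 mm pull held 400 ms
# within 1 s of the cue), per-trial behavioral metrics, and the selection
# rules feeding the population analysis.

leverTimes <- function(log) (seq_along(log@leverPosition) - 1) / log@rate

# Pull onset: the last sample at or below the noise floor (3 x baseline
# s.d.) before the threshold crossing. Baseline s.d. is estimated from
# pre-cue lever samples across the session.
noiseFloor <- function(log) {
  t <- leverTimes(log)
  pre <- rep(FALSE, length(t))
  for (ct in log@cueTimes) pre <- pre | (t >= ct - 0.5 & t < ct)
  base <- log@leverPosition[pre]
  if (!length(base)) base <- log@leverPosition
  3 * max(stats::sd(base), 1e-6)
}

#' Detect trials and score success from a behavior log
#'
#' A cue is successful iff the lever crosses \code{pullThreshold} within
#' \code{windowS} of cue onset and stays beyond the threshold continuously
#' for at least \code{holdS}. The pull onset is the last sub-noise-floor
#' sample before the threshold crossing; a pre-pull flag marks trials with
#' a sub-threshold excursion (> \code{prePullFraction} of the threshold)
#' between the cue and the successful pull onset. Trial selection for the
#' population analysis requires success, no pre-pull, and a reaction time
#' in \code{rtRange}.
#'
#' @param log a [BehaviorLog-class].
#' @param pullThreshold pull amplitude, mm.
#' @param holdS required hold duration, s.
#' @param windowS response window after cue onset, s.
#' @param prePullFraction pre-pull excursion threshold as a fraction of
#'   \code{pullThreshold}.
#' @param rtRange selected reaction-time range \code{c(lo, hi)}, s.
#' @return data.frame (one row per cue): cueTime, success, pullOnset,
#'   reactionTime, prePull, pullEnd, selected.
#' @export
detectTrials <- function(log, pullThreshold = 5, holdS = 0.4, windowS = 1.0,
                         prePullFraction = 0.2, rtRange = c(0.1, 0.5)) {
  stopifnot(is(log, "BehaviorLog"))
  cues <- sort(log@cueTimes)
  if (length(cues) > 1 && any(diff(cues) < windowS))
    stop("overlapping cue windows")
  lever <- log@leverPosition
  t <- leverTimes(log)
  if (length(cues) && max(cues) + windowS > max(t))
    stop("lever trace does not cover all cue windows")
  nf <- noiseFloor(log)
  rows <- lapply(cues, function(ct) {
    inWin <- which(t >= ct & t <= ct + windowS)
    success <- FALSE; onset <- NA_real_; prePull <- FALSE; pullEnd <- NA_real_
    crossIdx <- inWin[lever[inWin] >= pullThreshold]
    if (length(crossIdx)) {
      # walk candidate crossings until one sustains the hold
      for (ci in crossIdx) {
        if (ci > 1 && lever[ci - 1] >= pullThreshold) next  # not a crossing
        post <- which(t >= t[ci])
        below <- post[lever[post] < pullThreshold]
        holdEnd <- if (length(below)) t[below[1]] else max(t)
        if (holdEnd - t[ci] >= holdS) {
          success <- TRUE
          # onset: last sample at/below the noise floor before the crossing
          preIdx <- which(t < t[ci] & t >= ct)
          subIdx <- preIdx[lever[preIdx] <= nf]
          onset <- if (length(subIdx)) t[subIdx[length(subIdx)]] else ct
          pullEnd <- holdEnd
          # pre-pull: excursion beyond the fraction between cue and onset
          gapIdx <- which(t >= ct & t < onset)
          if (length(gapIdx) &&
              any(lever[gapIdx] > prePullFraction * pullThreshold))
            prePull <- TRUE
          break
        }
      }
    }
    rt <- if (success) onset - ct else NA_real_
    data.frame(cueTime = ct, success = success, pullOnset = onset,
      reactionTime = rt, prePull = prePull, pullEnd = pullEnd)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cueTime = numeric(0), success = logical(0),
      pullOnset = numeric(0), reactionTime = numeric(0),
      prePull = logical(0), pullEnd = numeric(0))
  out$selected <- out$success & !out$prePull &
    !is.na(out$reactionTime) &
    out$reactionTime >= rtRange[1] & out$reactionTime <= rtRange[2]
  out
}

# Per-trial lever trajectory snippets aligned to pull onset on a common
# relative clock.
trialTrajectories <- function(log, onsets, window) {
  t <- leverTimes(log)
  rel <- seq(window[1], window[2], by = 1 / log@rate)
  sapply(onsets, function(on) {
    stats::approx(t, log@leverPosition, xout = on + rel, rule = 1)$y
  })
}

#' Lever correlation: per-trial trajectory similarity to the session mean
#'
#' The template is the mean lever trajectory of all successful trials in
#' the alignment window (default -0.5 to 2.0 s around pull onset; the
#' behavioral-cluster analysis uses -0.43 to 1.85 s). Each trial's CC
#' against the template is returned; the session value is the mean of the
#' per-trial CCs.
#'
#' @param log a [BehaviorLog-class].
#' @param trials data.frame from [detectTrials()].
#' @param window alignment window \code{c(lo, hi)} in s around pull onset.
#' @return list with \code{perTrial} (CC per successful trial),
#'   \code{session} (their mean), \code{template}, \code{relTime}.
#' @export
leverCorrelation <- function(log, trials, window = c(-0.5, 2.0)) {
  ok <- trials$success & !is.na(trials$pullOnset)
  if (sum(ok) < 2) stop("at least 2 successful trials are required")
  traj <- trialTrajectories(log, trials$pullOnset[ok], window)
  good <- stats::complete.cases(t(traj))
  traj <- traj[, good, drop = FALSE]
  if (ncol(traj) < 2) stop("fewer than 2 trials fully covered by the window")
  template <- rowMeans(traj)
  per <- as.numeric(stats::cor(traj, template))
  rel <- seq(window[1], window[2], by = 1 / log@rate)
  list(perTrial = per, session = mean(per), template = template,
    relTime = rel)
}

#' Lever-pull speed at initiation
#'
#' Maximum finite-difference slope of the lever trajectory within
#' +/- \code{halfWindow} of the pull onset.
#'
#' @param log a [BehaviorLog-class].
#' @param trials data.frame from [detectTrials()].
#' @param halfWindow half-window, s.
#' @return numeric mm/s per trial (NA for trials without an onset or with
#'   a window outside the recording).
#' @export
pullSpeed <- function(log, trials, halfWindow = 0.1) {
  t <- leverTimes(log)
  lever <- log@leverPosition
  dt <- 1 / log@rate
  vapply(trials$pullOnset, function(on) {
    if (is.na(on)) return(NA_real_)
    if (on - halfWindow < min(t) || on + halfWindow > max(t)) return(NA_real_)
    idx <- which(t >= on - halfWindow & t <= on + halfWindow)
    if (length(idx) < 2) return(NA_real_)
    max(diff(lever[idx]) / dt)
  }, numeric(1))
}

#' Time elapsed since the previous reward
#'
#' @param trials data.frame from [detectTrials()].
#' @param rewardTimes reward delivery times, s.
#' @return numeric per trial: pull onset minus the latest prior reward;
#'   NA when no reward precedes the trial.
#' @export
timeFromPreviousReward <- function(trials, rewardTimes) {
  rewards <- sort(rewardTimes)
  vapply(trials$pullOnset, function(on) {
    if (is.na(on)) return(NA_real_)
    prior <- rewards[rewards < on]
    if (!length(prior)) return(NA_real_)
    on - max(prior)
  }, numeric(1))
}

#' Four behavioral properties per selected trial
#'
#' Convenience wrapper producing the property table used by
#' [behaviorPropertyClusters()]: pull speed, lever correlation
#' (window -0.43 to 1.85 s), reaction time, and time from previous
#' reward.
#'
#' @param log a [BehaviorLog-class].
#' @param trials data.frame from [detectTrials()].
#' @param leverWindow window for the lever correlation, s.
#' @return data.frame with one row per successful trial.
#' @export
behaviorProperties <- function(log, trials, leverWindow = c(-0.43, 1.85)) {
  ok <- trials$success & !is.na(trials$pullOnset)
  lc <- leverCorrelation(log, trials, leverWindow)
  sp <- pullSpeed(log, trials)[ok]
  tr <- timeFromPreviousReward(trials, log@rewardTimes)[ok]
  data.frame(
    trial = which(ok),
    pullSpeed = sp,
    leverCorrelation = lc$perTrial,
    reactionTime = trials$reactionTime[ok],
    timeFromPrevReward = tr
  )
}
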