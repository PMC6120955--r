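# Synthetic-data generators emulating every input the pipeline consumes,
# each exposing its ground truth so pipeline stages can be tested as
# parameter-recovery problems.

#' Session specification for the dual-area generator
#'
#' Defaults emulate the study conditions of the dual-area population
#' analysis: 46 and 24 movement-related neurons in the two areas, 65
#' selected trials per session, around ten latent trial clusters, a 30 Hz
#' native clock resampled through a 5.4 Hz-per-field interleaved dual
#' clock, and calcium decay constants of 1.40 s (RFA) and 1.22 s (CFA).
#' Coupling c is the probability that the CFA latent cluster identity of
#' a trial equals the RFA one.
#'
#' @param nNeurons integer(2), neurons per area (RFA, CFA).
#' @param nTrials trials per session.
#' @param kClusters latent cluster count.
#' @param coupling c in [0, 1].
#' @param eventRate baseline event rate, Hz.
#' @param moveGain mean extra rate of every movement-related neuron during
#'   the movement window, Hz.
#' @param clusterGain s.d. of the per-neuron cluster loadings, Hz.
#' @param latentDim dimension of the shared latent cluster geometry. The
#'   k cluster archetypes of both areas are projections of the same
#'   latent positions, so the between-cluster similarity structure is
#'   shared across areas (it is this geometry whose recovery the
#'   inter-cluster distance agreement measures).
#' @param tuningSd s.d. of the fixed per-neuron movement tuning, Hz. A
#'   neuron's typical movement response repeats across trials, so all
#'   trial population vectors share a common pattern; this sets the
#'   positive baseline trial-to-trial CC that the shuffle null exhibits.
#' @param tauS numeric(2), calcium decay constants per area, s.
#' @param noiseSd fluorescence noise s.d.
#' @param nativeRate native frame rate, Hz.
#' @param perFieldRate per-field dual-clock rate, Hz.
#' @param trialSpacingS onset-to-onset spacing, s.
#' @param seed RNG seed.
#' @return A validated list of class \code{sessionSpec}.
#' @export
sessionSpec <- function(nNeurons = c(46L, 24L), nTrials = 65L,
                        kClusters = 10L, coupling = 0.5, eventRate = 0.4,
                        moveGain = 1.2, clusterGain = 2.0,
                        tuningSd = 1.0, latentDim = 3L, tauS = c(1.40, 1.22),
                        noiseSd = 0.05, nativeRate = 30, perFieldRate = 5.4,
                        trialSpacingS = 8, seed = 1L) {
  stopifnot(coupling >= 0, coupling <= 1, all(tauS > 0), eventRate > 0,
    nTrials >= 2, kClusters >= 1, all(nNeurons >= 1))
  structure(list(nNeurons = as.integer(nNeurons), nTrials = as.integer(nTrials),
    kClusters = as.integer(kClusters), coupling = coupling,
    eventRate = eventRate, moveGain = moveGain, clusterGain = clusterGain,
    tuningSd = tuningSd, latentDim = as.integer(latentDim), tauS = tauS,
    noiseSd = noiseSd, nativeRate = nativeRate, perFieldRate = perFieldRate,
    trialSpacingS = trialSpacingS, seed = as.integer(seed)),
    class = "sessionSpec")
}

# exponential calcium kernel on the native clock, truncated at 5 tau
calciumKernel <- function(tau, rate) {
  t <- seq(0, 5 * tau, by = 1 / rate)
  exp(-t / tau)
}

genAreaEvents <- function(nNeurons, nFrames, rate, onsetIdx, clusterIds,
                          loadings, baselineRate, moveFrames, moveGain,
                          tuning) {
  v <- matrix(stats::rpois(nNeurons * nFrames, baselineRate / rate) *
    stats::rexp(nNeurons * nFrames), nNeurons, nFrames)
  for (tr in seq_along(onsetIdx)) {
    cl <- clusterIds[tr]
    idx <- onsetIdx[tr] + moveFrames
    idx <- idx[idx >= 1 & idx <= nFrames]
    lam <- pmax(baselineRate + moveGain + tuning + loadings[, cl] +
      stats::rnorm(nNeurons, 0, 0.1), 0.05) / rate
    add <- matrix(stats::rpois(nNeurons * length(idx), lam) *
      stats::rexp(nNeurons * length(idx)), nNeurons, length(idx))
    v[, idx] <- v[, idx] + add
  }
  v
}

#' Generate a dual-area trial-structured session
#'
#' Per trial the RFA latent cluster id is drawn uniformly; the CFA id
#' equals it with probability \code{coupling}, else is drawn uniformly.
#' A neuron's movement-window event rate is baseline + its loading on the
#' trial's cluster + noise; events are Poisson-count impulses with
#' exponential amplitudes on the native 30 Hz grid, and fluorescence is
#' the events convolved with the area's exponential calcium kernel plus
#' Gaussian noise. Per-cluster loadings are centered across neurons so
#' the field-averaged activity is comparable across clusters. The two
#' interleaved field clocks are offset by half a per-field period.
#'
#' @param spec a [sessionSpec()].
#' @param traces also synthesize fluorescence traces (skip for
#'   event-level analyses).
#' @return list with per-area \code{events} ([EventMatrix-class], native
#'   clock), \code{traces} ([TraceMatrix-class] or NULL), \code{onsets} (s),
#'   \code{fieldClocks} (list of the two interleaved clocks plus their
#'   union), and \code{groundTruth} (cluster ids per area, loadings).
#' @export
simulateDualAreaSession <- function(spec, traces = TRUE) {
  stopifnot(inherits(spec, "sessionSpec"))
  withr::with_seed(spec$seed, {
    rate <- spec$nativeRate
    spacing <- spec$trialSpacingS
    onsets <- 5 + spacing * (seq_len(spec$nTrials) - 1)
    duration <- max(onsets) + 5
    nFrames <- ceiling(duration * rate)
    onsetIdx <- round(onsets * rate) + 1L
    # movement window on the native clock, matching -0.46..+1.85 s
    moveFrames <- seq(round(-0.463 * rate), round(1.852 * rate))
    k <- spec$kClusters
    rfaCl <- sample.int(k, spec$nTrials, replace = TRUE)
    same <- stats::runif(spec$nTrials) < spec$coupling
    cfaCl <- ifelse(same, rfaCl, sample.int(k, spec$nTrials, replace = TRUE))
    d <- min(spec$latentDim, k)
    P <- matrix(stats::rnorm(d * k), d, k)  # shared latent cluster positions
    mkLoad <- function(n) {
      M <- matrix(stats::rnorm(n * d), n, d)
      L <- (M %*% P) * spec$clusterGain / sqrt(d)
      sweep(L, 2, colMeans(L))  # zero-sum per cluster: field average constant
    }
    loadR <- mkLoad(spec$nNeurons[1])
    loadC <- mkLoad(spec$nNeurons[2])
    tuneR <- stats::rnorm(spec$nNeurons[1], 0, spec$tuningSd)
    tuneC <- stats::rnorm(spec$nNeurons[2], 0, spec$tuningSd)
    evR <- genAreaEvents(spec$nNeurons[1], nFrames, rate, onsetIdx, rfaCl,
      loadR, spec$eventRate, moveFrames, spec$moveGain, tuneR)
    evC <- genAreaEvents(spec$nNeurons[2], nFrames, rate, onsetIdx, cfaCl,
      loadC, spec$eventRate, moveFrames, spec$moveGain, tuneC)
    mkFluor <- function(ev, tau) {
      kern <- calciumKernel(tau, rate)
      t(apply(ev, 1, function(x) {
        f <- stats::convolve(c(x, numeric(length(kern) - 1)),
          rev(kern), type = "open")
        f <- f[length(kern):(length(kern) + length(x) - 1)]
        f + stats::rnorm(length(x), 0, spec$noiseSd)
      }))
    }
    trR <- if (traces) mkFluor(evR, spec$tauS[1]) else NULL
    trC <- if (traces) mkFluor(evC, spec$tauS[2]) else NULL
    per <- 1 / spec$perFieldRate
    clockA <- seq(0, duration - per, by = per)
    clockB <- clockA + per / 2
    list(
      rfa = list(
        events = eventMatrix(evR, rate, unitIds = paste0("R", seq_len(nrow(evR)))),
        traces = if (traces) traceMatrix(trR, rate,
          unitIds = paste0("R", seq_len(nrow(trR)))) else NULL
      ),
      cfa = list(
        events = eventMatrix(evC, rate, unitIds = paste0("C", seq_len(nrow(evC)))),
        traces = if (traces) traceMatrix(trC, rate,
          unitIds = paste0("C", seq_len(nrow(trC)))) else NULL
      ),
      onsets = onsets,
      fieldClocks = list(a = clockA, b = clockB,
        union = sort(c(clockA, clockB))),
      groundTruth = list(rfaClusters = rfaCl, cfaClusters = cfaCl,
        loadingsRfa = loadR, loadingsCfa = loadC),
      spec = spec
    )
  })
}

#' Generate a soma-axon session with known parentage
#'
#' Each parent neuron's Poisson spike train is copied to its boutons with
#' per-event release failures, timing jitter and amplitude variation;
#' background boutons carry independent trains. Optionally renders a
#' movie in which the parent-derived boutons are Gaussian blobs along a
#' polyline (an axon) sharing the parent temporal signal.
#'
#' @param nParents parent somata.
#' @param boutonsPerParent boutons copied from each parent.
#' @param nBackground independent boutons.
#' @param rate parent event rate, Hz.
#' @param jitterS event timing jitter s.d., s.
#' @param amplitudeCV coefficient of variation of bouton event amplitudes.
#' @param releaseProb probability a parent event appears in a bouton.
#' @param durationS recording length, s.
#' @param frameRate clock, Hz.
#' @param movie logical; render the bouton movie.
#' @param movieDim \code{c(y, x)} pixels of the rendered field.
#' @param movieNoiseSd pixel noise s.d. of the rendered movie.
#' @param seed RNG seed.
#' @return list: \code{somata}, \code{boutons} ([EventMatrix-class]),
#'   \code{groundTruth$parentage} (parent index per bouton, NA for
#'   background), optional \code{movie} array \code{[frame, y, x]} and
#'   \code{axonPixels}.
#' @export
simulateSomaAxonSession <- function(nParents = 3L, boutonsPerParent = 7L,
                                    nBackground = 30L, rate = 0.5,
                                    jitterS = 0.1, amplitudeCV = 0.6,
                                    releaseProb = 0.8, durationS = 600,
                                    frameRate = 30, movie = FALSE,
                                    movieDim = c(40L, 60L),
                                    movieNoiseSd = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    nFrames <- ceiling(durationS * frameRate)
    trainOf <- function(r) {
      n <- stats::rpois(1, r * durationS)
      sort(stats::runif(n, 0, durationS))
    }
    toRow <- function(times, amps) {
      v <- numeric(nFrames)
      idx <- pmin(nFrames, pmax(1L, round(times * frameRate) + 1L))
      for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + amps[i]
      v
    }
    parents <- lapply(seq_len(nParents), function(i) {
      tt <- trainOf(rate)
      list(times = tt, amps = stats::rexp(length(tt)) + 0.5)
    })
    somaV <- t(vapply(parents, function(p) toRow(p$times, p$amps),
      numeric(nFrames)))
    parentage <- rep(NA_integer_, nParents * boutonsPerParent + nBackground)
    boutV <- matrix(0, nParents * boutonsPerParent + nBackground, nFrames)
    b <- 0L
    for (p in seq_len(nParents)) {
      for (jb in seq_len(boutonsPerParent)) {
        b <- b + 1L
        par <- parents[[p]]
        keep <- stats::runif(length(par$times)) < releaseProb
        tt <- par$times[keep] + stats::rnorm(sum(keep), 0, jitterS)
        amps <- par$amps[keep] *
          pmax(stats::rnorm(sum(keep), 1, amplitudeCV), 0.05)
        inside <- tt >= 0 & tt <= durationS
        boutV[b, ] <- toRow(tt[inside], amps[inside])
        parentage[b] <- p
      }
    }
    for (bg in seq_len(nBackground)) {
      b <- b + 1L
      tt <- trainOf(rate)
      boutV[b, ] <- toRow(tt, stats::rexp(length(tt)) + 0.5)
    }
    out <- list(
      somata = eventMatrix(somaV, frameRate,
        unitIds = paste0("soma", seq_len(nParents))),
      boutons = eventMatrix(boutV, frameRate,
        unitIds = paste0("bouton", seq_len(nrow(boutV)))),
      groundTruth = list(parentage = parentage)
    )
    if (movie) {
      ny <- movieDim[1]; nx <- movieDim[2]
      # polyline axon: left-to-right with a gentle sine wiggle
      xs <- seq(5, nx - 5, length.out = boutonsPerParent)
      ys <- round(ny / 2 + 6 * sin(seq(0, pi, length.out = boutonsPerParent)))
      sig <- somaV[1, ]
      sigF <- as.numeric(stats::filter(sig, rep(1 / 3, 3), sides = 2))
      sigF[is.na(sigF)] <- 0
      mv <- array(stats::rnorm(nFrames * ny * nx, 0, movieNoiseSd),
        dim = c(nFrames, ny, nx))
      blob <- function(cy, cx) {
        d <- outer(seq_len(ny), seq_len(nx),
          function(r, c2) exp(-((r - cy)^2 + (c2 - cx)^2) / (2 * 1.5^2)))
        d
      }
      axonMask <- matrix(FALSE, ny, nx)
      for (ib in seq_len(boutonsPerParent)) {
        g <- blob(ys[ib], round(xs[ib]))
        axonMask <- axonMask | g > 0.3
        for (fidx in seq_len(nFrames))
          mv[fidx, , ] <- mv[fidx, , ] + g * sigF[fidx]
      }
      out$movie <- mv
      out$axonPixels <- axonMask
      out$seedTrace <- sigF
    }
    out
  })
}

#' Generate a bead phantom volume
#'
#' Gaussian blobs with the requested FWHMs at random non-overlapping
#' positions on the stated voxel grid, plus Gaussian noise at the given
#' peak SNR, with the configured repeat frames per focal plane.
#'
#' @param fwhmUm named numeric \code{c(x=, y=, z=)}, planted FWHMs, um.
#' @param voxelUm named numeric \code{c(x=, y=, z=)}, voxel size, um.
#' @param dims named integer \code{c(x=, y=, z=)}, grid size in voxels.
#' @param nBeads bead count.
#' @param snr peak signal-to-noise ratio (Inf for noiseless).
#' @param framesPerPlane repeats per plane.
#' @param tiltDeg optional tilt of the bead's long (z) axis within the XZ
#'   plane, degrees.
#' @param seed RNG seed.
#' @return list: \code{frames} (raw \code{[frame, y, x]} array, repeats
#'   innermost), \code{volume} (the averaged [BeadVolume-class]),
#'   \code{groundTruth} (positions, planted FWHMs).
#' @export
simulateBeadVolume <- function(fwhmUm = c(x = 1.0, y = 1.0, z = 10.0),
                               voxelUm = c(x = 0.249, y = 0.249, z = 0.5),
                               dims = c(x = 41L, y = 41L, z = 81L),
                               nBeads = 1L, snr = 20, framesPerPlane = 5L,
                               tiltDeg = 0, seed = 1L) {
  stopifnot(all(fwhmUm >= 2 * voxelUm[names(fwhmUm)]))
  withr::with_seed(seed, {
    sig <- fwhmUm / FWHM_FACTOR
    nx <- dims["x"]; ny <- dims["y"]; nz <- dims["z"]
    xp <- (seq_len(nx) - 1) * voxelUm["x"]
    yp <- (seq_len(ny) - 1) * voxelUm["y"]
    zp <- (seq_len(nz) - 1) * voxelUm["z"]
    span <- c(max(xp), max(yp), max(zp))
    margin <- 1.5 * c(fwhmUm["x"], fwhmUm["y"], fwhmUm["z"])
    if (any(2 * margin >= span) && nBeads > 0)
      stop("volume too small for the requested bead size")
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(centers) < nBeads) {
      cand <- c(stats::runif(1, margin[1], span[1] - margin[1]),
        stats::runif(1, margin[2], span[2] - margin[2]),
        stats::runif(1, margin[3], span[3] - margin[3]))
      okSep <- !nrow(centers) ||
        all(sqrt(colSums((t(centers) - cand)^2)) > 3 * max(fwhmUm))
      if (okSep) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 1000L * max(1L, nBeads))
        stop("could not place beads without overlap (volume overcrowded)")
    }
    clean <- array(0, dim = c(nz, ny, nx))
    th <- deg2rad(tiltDeg)
    for (bI in seq_len(nBeads)) {
      cx <- centers[bI, 1]; cy <- centers[bI, 2]; cz <- centers[bI, 3]
      gx <- matrix(xp - cx, nz, nx, byrow = TRUE)
      gz <- matrix(zp - cz, nz, nx)
      # rotate the (x, z) frame by the tilt so the long axis leans in XZ
      u <- gx * cos(th) - gz * sin(th)   # short (x-like) axis
      w <- gx * sin(th) + gz * cos(th)   # long (z-like) axis
      xzPart <- exp(-u^2 / (2 * sig["x"]^2) - w^2 / (2 * sig["z"]^2))
      yPart <- exp(-(yp - cy)^2 / (2 * sig["y"]^2))
      for (yi in seq_len(ny))
        clean[, yi, ] <- clean[, yi, ] + xzPart * yPart[yi]
    }
    noiseSd <- if (is.finite(snr)) max(clean, 1e-12) / snr else 0
    nFrames <- nz * framesPerPlane
    frames <- array(0, dim = c(nFrames, ny, nx))
    for (z in seq_len(nz)) {
      for (r in seq_len(framesPerPlane)) {
        frames[(z - 1L) * framesPerPlane + r, , ] <- clean[z, , ] +
          if (noiseSd > 0) stats::rnorm(ny * nx, 0, noiseSd) else 0
      }
    }
    vol <- averagePlaneRepeats(frames, framesPerPlane, voxelUm)
    list(frames = frames, volume = vol,
      groundTruth = list(centersUm = centers, fwhmUm = fwhmUm,
        tiltDeg = tiltDeg))
  })
}

#' Generate a behavior log with planted trial outcomes
#'
#' Lever traces are built per trial from a template pull (rise to the
#' target amplitude, hold, return) plus Gaussian noise; trials are
#' planted as successes (hold >= 400 ms), hold failures, or late pulls,
#' with an optional pre-pull excursion, and cue intervals are drawn
#' uniformly from 2.5-3.5 s after lever return.
#'
#' @param nTrials trial count.
#' @param successFraction fraction of planted successes.
#' @param prePullFraction fraction of successful trials with a planted
#'   pre-pull.
#' @param rtMean,rtSd reaction-time distribution, s (truncated to
#'   \code{[0.05, 0.9]}).
#' @param pullAmplitude peak lever excursion, mm.
#' @param holdS planted hold duration for successes, s.
#' @param noiseSd lever noise s.d., mm.
#' @param rate sampling rate, Hz.
#' @param seed RNG seed.
#' @return list: \code{log} ([BehaviorLog-class]), \code{groundTruth}
#'   data.frame (cueTime, success, prePull, plantedRT).
#' @export
simulateBehaviorLog <- function(nTrials = 65L, successFraction = 0.85,
                                prePullFraction = 0.1, rtMean = 0.2,
                                rtSd = 0.05, pullAmplitude = 6,
                                holdS = 0.6, noiseSd = 0.02, rate = 100,
                                seed = 1L) {
  withr::with_seed(seed, {
    dt <- 1 / rate
    segs <- list()
    gt <- list()
    tcur <- 1.0
    lever <- numeric(round(tcur * rate))
    cueTimes <- numeric(0)
    rewardTimes <- numeric(0)
    riseS <- 0.15
    for (tr in seq_len(nTrials)) {
      cue <- tcur
      cueTimes <- c(cueTimes, cue)
      success <- stats::runif(1) < successFraction
      prePull <- success && stats::runif(1) < prePullFraction
      rt <- min(max(stats::rnorm(1, rtMean, rtSd), 0.05), 0.9)
      hold <- if (success) holdS else 0.2  # failed trials hold too briefly
      # segment: cue .. onset (flat, maybe pre-pull), pull, hold, return
      flatN <- round(rt * rate)
      flat <- numeric(flatN)
      if (prePull && flatN > 6) {
        pp <- round(flatN / 2)
        flat[pp:(pp + 2)] <- 0.35 * 5  # short sub-threshold excursion
      }
      riseN <- round(riseS * rate)
      rise <- seq(0, pullAmplitude, length.out = riseN)
      holdN <- round(hold * rate)
      holdSeg <- rep(pullAmplitude, holdN)
      fallN <- round(0.2 * rate)
      fall <- seq(pullAmplitude, 0, length.out = fallN)
      iti <- stats::runif(1, 2.5, 3.5)
      itiN <- round(iti * rate)
      seg <- c(flat, rise, holdSeg, fall, numeric(itiN))
      lever <- c(lever, seg)
      if (success) {
        rewardTimes <- c(rewardTimes, cue + rt + riseS + hold)
      }
      gt[[tr]] <- data.frame(cueTime = cue, success = success,
        prePull = prePull, plantedRT = rt)
      tcur <- tcur + length(seg) * dt
    }
    lever <- lever + stats::rnorm(length(lever), 0, noiseSd)
    log <- behaviorLog(lever, rate, cueTimes, rewardTimes)
    list(log = log, groundTruth = do.call(rbind, gt))
  })
}
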