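# Trial-to-trial population covariation between two areas:
# movement-related classification, population vectors, affinity-propagation
# clustering of trials, cross-area intra-cluster correlation with a
# shuffle null, and inter-cluster distance agreement.

#' Classify neurons as movement related
#'
#' For every neuron, samples of the (resampled) inferred spike events are
#' pooled over the movement-related window of all trials (-5 to +20
#' resampled frames around pull onset at 10.8 Hz, i.e. about -0.46 to
#' +1.85 s) and over the resting window (-25 to -10 frames), and compared
#' with a one-sided Wilcoxon rank-sum test. A neuron is movement related
#' iff p < alpha with the movement side larger. Trials whose windows fall
#' outside the recording are dropped with a log message.
#'
#' @param ev an [EventMatrix-class] on the resampled clock.
#' @param onsets pull-onset times, s.
#' @param moveWin,restWin windows in resampled frames relative to onset.
#' @param alpha significance level.
#' @param twoSided use a two-sided test instead of one-sided.
#' @return logical mask, one entry per neuron; attribute
#'   \code{droppedTrials} lists onsets excluded for truncation.
#' @export
classifyMovementRelated <- function(ev, onsets, moveWin = c(-5, 20),
                                    restWin = c(-25, -10), alpha = 0.05,
                                    twoSided = FALSE) {
  stopifnot(is(ev, "TraceMatrix"))
  t <- frameTimes(ev)
  n <- ncol(ev@values)
  onsetIdx <- vapply(onsets, function(on) which.min(abs(t - on)), integer(1))
  lo <- min(moveWin[1], restWin[1]); hi <- max(moveWin[2], restWin[2])
  okTrial <- onsetIdx + lo >= 1L & onsetIdx + hi <= n
  if (!all(okTrial))
    message(sum(!okTrial), " trial(s) truncated by the recording edge; dropped")
  onsetIdx <- onsetIdx[okTrial]
  if (!length(onsetIdx)) stop("no trial windows fit within the recording")
  moveIdx <- as.vector(outer(moveWin[1]:moveWin[2], onsetIdx, `+`))
  restIdx <- as.vector(outer(restWin[1]:restWin[2], onsetIdx, `+`))
  mask <- vapply(seq_len(nrow(ev@values)), function(i) {
    mv <- ev@values[i, moveIdx]
    rs <- ev@values[i, restIdx]
    alt <- if (twoSided) "two.sided" else "greater"
    p <- suppressWarnings(stats::wilcox.test(mv, rs, alternative = alt)$p.value)
    isTRUE(p < alpha) && stats::median(mv) >= stats::median(rs)
  }, logical(1))
  attr(mask, "droppedTrials") <- which(!okTrial)
  mask
}

#' Build the trial population-activity matrix of one area
#'
#' Each movement-related neuron is z-scored over the full session clock,
#' the movement-related window of every selected trial is sliced out, and
#' the time dimension is averaged, giving one cells x trials matrix whose
#' columns are trial population vectors. Zero-variance neurons cannot be
#' z-scored and are excluded with a log message.
#'
#' @param ev an [EventMatrix-class] on the resampled clock.
#' @param onsets pull-onset times of the selected trials, s.
#' @param relatedMask logical mask from [classifyMovementRelated()]
#'   (default: all neurons).
#' @param moveWin movement-related window in resampled frames.
#' @param area area label carried into the result.
#' @return A [PopulationMatrix-class].
#' @export
buildPopulationMatrix <- function(ev, onsets, relatedMask = NULL,
                                  moveWin = c(-5, 20), area = "NA") {
  stopifnot(is(ev, "TraceMatrix"))
  if (is.null(relatedMask)) relatedMask <- rep(TRUE, nrow(ev@values))
  v <- ev@values[relatedMask, , drop = FALSE]
  ids <- ev@unitIds[relatedMask]
  if (!nrow(v)) stop("no movement-related neurons")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance neuron(s) excluded")
    v <- v[sds > 0, , drop = FALSE]
    ids <- ids[sds > 0]
  }
  if (!nrow(v)) stop("all neurons have zero variance")
  z <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  t <- frameTimes(ev)
  n <- ncol(v)
  onsetIdx <- vapply(onsets, function(on) which.min(abs(t - on)), integer(1))
  ok <- onsetIdx + moveWin[1] >= 1L & onsetIdx + moveWin[2] <= n
  if (sum(ok) < 2) stop("at least 2 trials with complete windows are required")
  onsetIdx <- onsetIdx[ok]
  cols <- vapply(onsetIdx, function(oi)
    rowMeans(z[, (oi + moveWin[1]):(oi + moveWin[2]), drop = FALSE]),
    numeric(nrow(z)))
  if (nrow(z) == 1L) cols <- matrix(cols, nrow = 1)
  populationMatrix(area, cols, trialIds = which(ok), cellIds = ids)
}

#' Trial-pair similarity matrix
#'
#' Pearson correlation over cells between trial population vectors
#' (\code{"cc"}), or the negative squared Euclidean distance
#' (\code{"neg_sq_euclidean"}). The CC is sensitive only to the angle
#' between population vectors; the Euclidean variant also sees scaling.
#'
#' @param pm a [PopulationMatrix-class] (or a plain cells x trials matrix).
#' @param kind similarity definition.
#' @return trials x trials symmetric matrix; undefined CC entries (a
#'   zero-variance trial column) are NA.
#' @export
trialSimilarityMatrix <- function(pm, kind = c("cc", "neg_sq_euclidean")) {
  kind <- match.arg(kind)
  v <- if (is(pm, "PopulationMatrix")) pm@values else as.matrix(pm)
  if (kind == "cc") {
    if (nrow(v) < 2) stop("at least 2 cells are required for CC similarity")
    sds <- apply(v, 2, stats::sd)
    S <- suppressWarnings(stats::cor(v))
    if (any(sds == 0)) {
      S[sds == 0, ] <- NA; S[, sds == 0] <- NA
    }
    S
  } else {
    G <- crossprod(v)
    d2 <- outer(diag(G), diag(G), `+`) - 2 * G
    -pmax(d2, 0)
  }
}

#' Affinity-propagation clustering
#'
#' Exemplar-based clustering by responsibility/availability message
#' passing with damping. The preference (self-similarity, the diagonal of
#' S) defaults to the median of the off-diagonal similarities; percentile
#' rules mirror the robustness variants (a lower percentile yields fewer
#' clusters). Deterministic given S and parameters: exact ties break
#' toward the lowest index.
#'
#' @param S square symmetric similarity matrix (larger = more similar).
#' @param preference \code{"median"}, a quantile in (0,1) given as
#'   \code{list(percentile = p)}, or an explicit numeric value.
#' @param damping damping factor in [0.5, 1).
#' @param maxIter maximum message-passing iterations.
#' @param stableIter iterations with unchanged exemplar set required to
#'   declare convergence.
#' @return A [ClusterResult-class]; \code{converged} is FALSE when the
#'   exemplar set was still changing at \code{maxIter} (a warning is
#'   raised but the result is returned).
#' @export
affinityPropagation <- function(S, preference = "median", damping = 0.9,
                                maxIter = 1000L, stableIter = 100L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (anyNA(S)) stop("similarity matrix contains undefined entries")
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) stats::median(off)
    else if (is.list(preference)) stats::quantile(off, preference$percentile,
      names = FALSE)
    else as.numeric(preference)
  diag(S) <- pref
  # ties break toward the lowest index via max.col/which.max below
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  lastEx <- NULL; stable <- 0L; it <- 0L
  for (it in seq_len(maxIter)) {
    # responsibilities
    AS <- A + S
    m1 <- apply(AS, 1, max)
    w1 <- max.col(AS, ties.method = "first")
    ASt <- AS
    ASt[cbind(seq_len(n), w1)] <- -Inf
    m2 <- apply(ASt, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), w1)] <- S[cbind(seq_len(n), w1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colSums_ <- colSums(Rp)
    Anew <- matrix(colSums_, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, lastEx)) stable <- stable + 1L else stable <- 0L
    lastEx <- ex
    if (stable >= stableIter) break
  }
  converged <- stable >= stableIter
  ex <- lastEx
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  # assign each point to its best exemplar; exemplars label themselves
  assign <- apply(S[, ex, drop = FALSE], 1, which.max)
  assign[ex] <- seq_along(ex)
  if (!converged)
    warning("affinity propagation did not converge within ", maxIter,
      " iterations")
  new("ClusterResult", labels = as.integer(assign),
    exemplars = as.integer(ex), k = length(ex),
    similarity = "custom", preference = pref, damping = damping,
    iterations = as.integer(it), converged = converged)
}

# mean pairwise similarity within clusters, averaged over non-singleton
# clusters; CCmat is the full trial CC matrix, labels an integer vector.
intraClusterStatistic <- function(CCmat, labels) {
  vals <- c()
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < 2) next
    sub <- CCmat[members, members]
    vals <- c(vals, mean(sub[upper.tri(sub)]))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Cross-area intra-cluster correlation with a shuffle null
#'
#' Trials are grouped by one area's clustering; within each (non-
#' singleton) cluster, the mean pairwise CC of the *other* area's trial
#' population vectors is computed and averaged across clusters. The null
#' permutes the trial-to-cluster assignment and averages the same
#' statistic over \code{nShuffles} permutations (the mean over shuffles is
#' the reported null value, per the 1000-shuffle procedure).
#'
#' @param clusterSource a [ClusterResult-class] from the source area.
#' @param target a [PopulationMatrix-class] of the target area, on the
#'   same trials.
#' @param nShuffles number of label permutations.
#' @param seed RNG seed for the permutations.
#' @param shuffleTrials permute target trial identities instead of the
#'   cluster-assignment map (alternative reading of the procedure).
#' @return list: \code{intraCC}, \code{nullMean}, \code{nullValues}
#'   (length \code{nShuffles}), \code{perCluster} (named numeric, NA for
#'   singletons).
#' @export
crossAreaIntraClusterCC <- function(clusterSource, target, nShuffles = 1000L,
                                    seed = 1L, shuffleTrials = FALSE) {
  stopifnot(is(clusterSource, "ClusterResult"), is(target, "PopulationMatrix"))
  labels <- clusterSource@labels
  if (length(labels) != ncol(target@values))
    stop("clusters must come from the same trial set as the target columns")
  if (all(tabulate(labels) < 2)) stop("all clusters are singletons")
  CCmat <- trialSimilarityMatrix(target, "cc")
  intra <- intraClusterStatistic(CCmat, labels)
  perCluster <- vapply(sort(unique(labels)), function(cl) {
    m <- which(labels == cl)
    if (length(m) < 2) return(NA_real_)
    sub <- CCmat[m, m]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(perCluster) <- paste0("cluster", sort(unique(labels)))
  nullValues <- withr::with_seed(seed, {
    vapply(seq_len(nShuffles), function(s) {
      perm <- sample(length(labels))
      if (shuffleTrials)
        intraClusterStatistic(CCmat[perm, perm], labels)
      else
        intraClusterStatistic(CCmat, labels[perm])
    }, numeric(1))
  })
  list(intraCC = intra, nullMean = mean(nullValues),
    nullValues = nullValues, perCluster = perCluster)
}

#' Inter-cluster distance matrix of one area
#'
#' Cluster-mean population vectors, compared pairwise by CC (default) or
#' Euclidean distance. A singleton cluster's mean is its single vector.
#'
#' @param pm a [PopulationMatrix-class].
#' @param clusters a [ClusterResult-class] on the same trials.
#' @param metric \code{"cc"} or \code{"euclidean"}.
#' @return k x k symmetric matrix (unit diagonal for CC, zero for
#'   Euclidean).
#' @export
interClusterDistances <- function(pm, clusters, metric = c("cc", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is(pm, "PopulationMatrix"), is(clusters, "ClusterResult"))
  labels <- clusters@labels
  if (clusters@k < 2) stop("at least 2 clusters are required")
  means <- vapply(seq_len(clusters@k), function(cl)
    rowMeans(pm@values[, labels == cl, drop = FALSE]),
    numeric(nrow(pm@values)))
  if (nrow(pm@values) == 1L) means <- matrix(means, nrow = 1)
  out <- if (metric == "cc") stats::cor(means)
    else as.matrix(stats::dist(t(means)))
  dimnames(out) <- NULL
  out
}

#' Agreement between two areas' inter-cluster distance matrices
#'
#' Pearson r (plus regression slope and intercept) between the vectorized
#' off-diagonal upper triangles of the two k x k matrices, which must
#' index the same clusters.
#'
#' @param mA,mB k x k matrices from [interClusterDistances()].
#' @return list: \code{r}, \code{slope}, \code{intercept}, \code{n} pairs.
#' @export
clusterDistanceAgreement <- function(mA, mB) {
  if (!all(dim(mA) == dim(mB))) stop("matrices must share dimensions")
  k <- nrow(mA)
  if (k < 3) stop("at least 3 clusters are required for a correlation")
  a <- mA[upper.tri(mA)]
  b <- mB[upper.tri(mB)]
  fit <- stats::lm(b ~ a)
  list(r = stats::cor(a, b), slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]), n = length(a))
}

#' Cluster trials by behavioral properties
#'
#' Standardizes the four behavioral properties (pull speed, lever
#' correlation, reaction time, time from previous reward), builds a
#' trial-pair similarity over the 4-vectors, and runs affinity propagation
#' with the median preference. Trials with undefined properties are
#' excluded with a log message.
#'
#' @param properties data.frame from [behaviorProperties()] (columns
#'   pullSpeed, leverCorrelation, reactionTime, timeFromPrevReward).
#' @param kind similarity definition as in [trialSimilarityMatrix()].
#' @param ... passed to [affinityPropagation()].
#' @return list with \code{clusters} ([ClusterResult-class]) and
#'   \code{usedTrials}, the row indices retained.
#' @export
behaviorPropertyClusters <- function(properties,
                                     kind = c("cc", "neg_sq_euclidean"),
                                     ...) {
  kind <- match.arg(kind)
  cols <- c("pullSpeed", "leverCorrelation", "reactionTime",
    "timeFromPrevReward")
  if (!all(cols %in% names(properties)))
    stop("properties must contain: ", paste(cols, collapse = ", "))
  P <- as.matrix(properties[, cols])
  ok <- stats::complete.cases(P)
  if (any(!ok)) message(sum(!ok), " trial(s) with undefined properties excluded")
  P <- P[ok, , drop = FALSE]
  Pz <- scale(P)
  Pz[, apply(P, 2, stats::sd) == 0] <- 0
  S <- trialSimilarityMatrix(t(Pz), kind)
  if (anyNA(S)) {
    # identical standardized 4-vectors across a zero-variance property set
    S[is.na(S)] <- 1
  }
  cl <- affinityPropagation(S, ...)
  list(clusters = cl, usedTrials = which(ok))
}
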