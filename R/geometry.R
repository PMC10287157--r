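## Population geometry: peak-aligned trial tensors, per-context PCA
## manifolds, and principal angles with a resampled control distribution.

#' Build peak-aligned trial tensors
#'
#' Bins SBP at 20 ms, masks channels to mean TCFR > 1 Hz, aligns every
#' analysis trial to the bin containing its peak movement, and extracts a
#' window from 400 ms before to 740 ms after that bin (20 + 1 + 37 = 58
#' bins). Returns the per-trial window array plus trial-averaged
#' per-context tensors and a condition-balanced array for demixed PCA.
#'
#' @param session a [SessionRecord-class].
#' @param contexts contexts to include (default: all present).
#' @param binWidthMs bin width (20 ms).
#' @param nBefore,nAfter window extent in bins (20, 37).
#' @param tcfrMaskHz channel mask threshold (1 Hz).
#' @param balanceSeed seed for subsampling conditions to equal trial
#'   counts in the balanced array.
#' @param smooth apply the 100 ms Gaussian kernel before windowing.
#' @return list: `windows` (channels x bins x trials array), `context`,
#'   `target` (per-trial labels), `avg` (list per context: channels x
#'   bins x targets), `balanced` (channels x contexts x targets x bins x
#'   n array), `mask`, `targets`, `contexts`, `peakBins`.
#' @export
buildTrialTensor <- function(session, contexts = NULL, binWidthMs = 20L,
                             nBefore = 20L, nAfter = 37L, tcfrMaskHz = 1,
                             balanceSeed = 1L, smooth = TRUE) {
  st <- streams(session)
  tr <- selectAnalysisTrials(session)
  if (is.null(contexts)) contexts <- unique(tr$context)
  tr <- tr[tr$context %in% contexts & tr$target_center_index != 50, ,
           drop = FALSE]
  if (!nrow(tr)) .stopf("buildTrialTensor: no out-target analysis trials")

  sbp <- binSBP(st, binWidthMs)
  if (smooth) sbp <- gaussianSmooth(sbp)
  tc <- binTCFR(st@crossingTimes, binWidthMs, nrow(st@sbp1ms),
                originMs = st@originMs)
  mask <- colMeans(featureValues(tc)) > tcfrMaskHz
  V <- featureValues(sbp)[, mask, drop = FALSE]
  kin <- savgolVelocity(st@fingerPosition, originMs = st@originMs)

  nCh <- ncol(V); Tw <- nBefore + 1L + nAfter
  keep <- logical(nrow(tr)); peakBins <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    pk <- findPeakMovement(kin$velocity, tr$presentation_time_ms[i],
                           tr$end_time_ms[i])
    peakBins[i] <- pk$peakBinIndex
    keep[i] <- pk$peakBinIndex - nBefore >= 1 &&
      pk$peakBinIndex + nAfter <= nrow(V)
  }
  tr <- tr[keep, , drop = FALSE]; peakBins <- peakBins[keep]
  if (!nrow(tr))
    .stopf("buildTrialTensor: no trial provides the full %d-bin window", Tw)
  windows <- array(NA_real_, c(nCh, Tw, nrow(tr)))
  for (i in seq_len(nrow(tr)))
    windows[, , i] <- t(V[(peakBins[i] - nBefore):(peakBins[i] + nAfter), ,
                          drop = FALSE])
  target <- ifelse(tr$target_center_index > 50, "flexion", "extension")

  ctxs <- intersect(contexts, unique(tr$context))
  tgts <- sort(unique(target))
  avg <- lapply(ctxs, function(cx) {
    arr <- array(NA_real_, c(nCh, Tw, length(tgts)))
    for (d in seq_along(tgts)) {
      sel <- which(tr$context == cx & target == tgts[d])
      if (!length(sel))
        .stopf("buildTrialTensor: condition (%s, %s) has zero trials",
               cx, tgts[d])
      arr[, , d] <- apply(windows[, , sel, drop = FALSE], c(1, 2), mean)
    }
    arr
  })
  names(avg) <- ctxs

  counts <- table(tr$context, target)
  nMin <- min(counts[ctxs, tgts])
  balanced <- array(NA_real_, c(nCh, length(ctxs), length(tgts), Tw, nMin))
  .withSeed(balanceSeed, "balance", {
    for (ci in seq_along(ctxs)) for (d in seq_along(tgts)) {
      sel <- which(tr$context == ctxs[ci] & target == tgts[d])
      sel <- if (length(sel) > nMin) sample(sel, nMin) else sel
      balanced[, ci, d, , ] <- aperm(windows[, , sel, drop = FALSE],
                                     c(1, 2, 3))
    }
  })
  list(windows = windows, context = tr$context, target = target,
       avg = avg, balanced = balanced, mask = mask,
       targets = tgts, contexts = ctxs, peakBins = peakBins,
       trialIndex = tr$trial_index)
}

#' Fit a per-context PCA manifold
#'
#' Reshapes a channels x bins x targets tensor to channels x (bins *
#' targets), removes channel means, and keeps the top-K principal
#' components of the channel covariance.
#'
#' @param tensor channels x bins x targets array (or channels x anything
#'   matrix).
#' @param K number of components.
#' @param context label stored on the manifold.
#' @return a [ContextManifold-class].
#' @export
fitPCAManifold <- function(tensor, K, context = "unknown") {
  M <- if (length(dim(tensor)) == 3) matrix(tensor, nrow = dim(tensor)[1])
       else as.matrix(tensor)
  Mc <- M - rowMeans(M)
  s <- svd(Mc, nu = min(K, nrow(Mc)), nv = 0)
  ev <- s$d^2 / sum(s$d^2)
  obj <- new("ContextManifold")
  obj@basis <- s$u[, seq_len(K), drop = FALSE]
  obj@explainedVariance <- ev[seq_len(K)]
  obj@context <- context
  validObject(obj)
  obj
}

#' Principal angles between two subspaces
#'
#' Ascending angles (degrees) whose cosines are the singular values of
#' `t(basisA) %*% basisB`. Non-orthonormal inputs are re-orthonormalized
#' with a warning. Symmetric in its arguments and invariant to
#' right-rotation of either basis.
#'
#' @param basisA,basisB channels x K orthonormal matrices (or
#'   [ContextManifold-class] objects).
#' @return numeric vector of length `min(K_A, K_B)`, in \[0, 90\] degrees.
#' @export
principalAngles <- function(basisA, basisB) {
  A <- if (is(basisA, "ContextManifold")) basisA@basis else basisA
  B <- if (is(basisB, "ContextManifold")) basisB@basis else basisB
  reorth <- function(M, label) {
    g <- crossprod(M)
    if (max(abs(g - diag(ncol(M)))) > 1e-8) {
      .warnf("principalAngles: %s basis not orthonormal, re-orthonormalized",
             label)
      qr.Q(qr(M))
    } else M
  }
  A <- reorth(A, "first"); B <- reorth(B, "second")
  if (nrow(A) != nrow(B))
    .stopf("principalAngles: bases live in different ambient dimensions")
  sv <- svd(crossprod(A, B), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(sv, -1), 1)) * 180 / pi)
}

#' Control distribution of principal angles from normal trials
#'
#' Per repetition, draws two disjoint random sets of `setSize` normal
#' trials (without replacement), computes a trial-averaged manifold from
#' each, and records their principal angles. The per-rank mean and
#' standard deviation form the control band against which off-context
#' angles are judged.
#'
#' @param tensor result of [buildTrialTensor()].
#' @param K manifold dimensionality.
#' @param setSize trials per set (default 50).
#' @param reps repetitions (default 100).
#' @param seed RNG seed.
#' @return list: `angles` (reps x K matrix), `mean`, `sd` (per rank).
#' @export
controlAngleDistribution <- function(tensor, K, setSize = 50L, reps = 100L,
                                     seed = 1L) {
  normalIdx <- which(tensor$context == "normal")
  if (length(normalIdx) < 2 * setSize)
    .stopf("controlAngleDistribution: need at least %d normal trials",
           2 * setSize)
  tgt <- tensor$target[normalIdx]
  angles <- .withSeed(seed, "control-angles", {
    t(vapply(seq_len(reps), function(r) {
      sel <- sample(normalIdx, 2 * setSize)
      s1 <- sel[seq_len(setSize)]; s2 <- sel[-seq_len(setSize)]
      m1 <- .setManifold(tensor, s1, K)
      m2 <- .setManifold(tensor, s2, K)
      principalAngles(m1, m2)
    }, numeric(K)))
  })
  if (reps == 1) angles <- matrix(angles, 1)
  list(angles = angles, mean = colMeans(angles),
       sd = if (reps > 1) apply(angles, 2, stats::sd) else rep(NA_real_, K))
}

# Manifold from a specific trial subset, averaging per target.
.setManifold <- function(tensor, sel, K) {
  tgts <- tensor$targets
  nCh <- dim(tensor$windows)[1]; Tw <- dim(tensor$windows)[2]
  arr <- array(NA_real_, c(nCh, Tw, length(tgts)))
  for (d in seq_along(tgts)) {
    sd_ <- sel[tensor$target[sel] == tgts[d]]
    if (!length(sd_)) sd_ <- sel
    arr[, , d] <- apply(tensor$windows[, , sd_, drop = FALSE], c(1, 2), mean)
  }
  fitPCAManifold(arr, K)
}

#' Principal angles of every off-context manifold to the normal manifold
#'
#' @param tensor result of [buildTrialTensor()].
#' @param K manifold dimensionality (16 by default).
#' @return list per off-context of angle vectors, plus the control band
#'   from [controlAngleDistribution()] when enough normal trials exist.
#' @export
contextPrincipalAngles <- function(tensor, K = 16L, setSize = 50L,
                                   reps = 100L, seed = 1L) {
  normalM <- fitPCAManifold(tensor$avg[["normal"]], K, "normal")
  offs <- setdiff(tensor$contexts, "normal")
  angles <- lapply(offs, function(cx)
    principalAngles(normalM, fitPCAManifold(tensor$avg[[cx]], K, cx)))
  names(angles) <- offs
  control <- if (sum(tensor$context == "normal") >= 2 * setSize)
    controlAngleDistribution(tensor, K, setSize, reps, seed) else NULL
  list(angles = angles, control = control, K = K)
}
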