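## Demixed PCA: marginalize the condition-averaged tensor into
## condition-independent (time), context, target, and interaction parts
## whose sum reconstructs the centered averages exactly, then find paired
## decoder/encoder maps per marginalization by regularized reduced-rank
## regression.

# Exact additive marginalization of a centered N x C x D x T array.
.marginalize <- function(Xc) {
  dms <- dim(Xc)
  N <- dms[1]; Cn <- dms[2]; Dn <- dms[3]; Tn <- dms[4]
  Mt <- apply(Xc, c(1, 4), mean)                       # N x T
  Et <- aperm(array(Mt, c(N, Tn, Cn, Dn)), c(1, 3, 4, 2))
  Mc <- apply(Xc, c(1, 2, 4), mean)                    # N x C x T
  Ec <- aperm(array(Mc, c(N, Cn, Tn, Dn)), c(1, 2, 4, 3)) - Et
  Md <- apply(Xc, c(1, 3, 4), mean)                    # N x D x T
  Ed <- aperm(array(Md, c(N, Dn, Tn, Cn)), c(1, 4, 2, 3)) - Et
  Ei <- Xc - Et - Ec - Ed
  list(condition_independent = Et, context = Ec, target = Ed,
       interaction = Ei)
}

#' Marginalization variance fractions of a condition tensor
#'
#' Decomposes the centered condition averages into condition-independent
#' (time), context, target, and context-target interaction parts and
#' returns each part's share of the total variance. The parts are
#' mutually orthogonal under the averaging inner product, so the
#' fractions sum to 1 exactly.
#'
#' @param tensor channels x contexts x targets x bins condition-average
#'   array, or a [buildTrialTensor()] result (its balanced array is
#'   averaged over trials).
#' @return named numeric vector of fractions summing to 1.
#' @export
marginalizationVariance <- function(tensor) {
  Xc <- .centeredAverages(tensor)
  parts <- .marginalize(Xc)
  tot <- sum(Xc^2)
  vapply(parts, function(p) sum(p^2) / tot, numeric(1))
}

.centeredAverages <- function(tensor) {
  Xbar <- if (is.list(tensor)) apply(tensor$balanced, 1:4, mean) else tensor
  if (length(dim(Xbar)) != 4)
    .stopf("expected a channels x contexts x targets x bins array")
  Xbar - c(apply(Xbar, 1, mean))
}

#' Fit demixed PCA
#'
#' Components per marginalization minimize the regularized reconstruction
#' error of that marginalization from the full centered averages via
#' reduced-rank ridge regression (SVD of the fitted regression).
#' The total of `nComponents` is split across marginalizations
#' proportionally to their variance fractions (at least one each where
#' variance is nonzero) unless `ranks` overrides the allocation.
#'
#' @param tensor condition tensor as in [marginalizationVariance()].
#' @param nComponents total components (default 16).
#' @param regularization ridge penalty as a fraction of total variance
#'   (default 1e-6).
#' @param ranks optional named integer vector of per-marginalization
#'   ranks overriding the proportional allocation.
#' @return a [DPCAResult-class].
#' @export
dpcaFit <- function(tensor, nComponents = 16L, regularization = 1e-6,
                    ranks = NULL) {
  Xc <- .centeredAverages(tensor)
  N <- dim(Xc)[1]
  parts <- .marginalize(Xc)
  vf <- vapply(parts, function(p) sum(p^2), numeric(1))
  vf <- vf / sum(vf)

  if (is.null(ranks)) {
    ranks <- round(vf * nComponents)
    ranks[ranks < 1] <- 1L
    # trim/grow to the exact total, adjusting the largest allocations
    while (sum(ranks) > nComponents) {
      i <- which.max(ranks); ranks[i] <- ranks[i] - 1L
    }
    while (sum(ranks) < nComponents) {
      i <- which.max(vf / ranks); ranks[i] <- ranks[i] + 1L
    }
  }
  ranks <- ranks[names(parts)]

  Z <- matrix(Xc, N)                       # N x (C*D*T)
  lam <- regularization * sum(Z^2)
  G <- tcrossprod(Z) + diag(lam, N)
  Ginv <- chol2inv(chol(G))

  encoder <- NULL; decoder <- NULL
  marg <- character(0); varComp <- numeric(0)
  tot <- sum(Z^2)
  for (m in names(parts)) {
    q <- ranks[[m]]
    if (q < 1) next
    Zm <- matrix(parts[[m]], N)
    A <- Zm %*% crossprod(Z, Ginv)         # N x N regression map
    P <- A %*% Z
    s <- svd(P, nu = q, nv = 0)
    Fm <- s$u[, seq_len(q), drop = FALSE]
    Dm <- crossprod(Fm, A)                 # q x N decoder
    encoder <- cbind(encoder, Fm)
    decoder <- rbind(decoder, Dm)
    marg <- c(marg, rep(m, q))
    varComp <- c(varComp, s$d[seq_len(q)]^2 / tot)
  }
  obj <- new("DPCAResult")
  obj@encoder <- encoder
  obj@decoder <- decoder
  obj@componentMarg <- marg
  obj@varFractionComponent <- varComp
  obj@varFractionMarg <- vf
  obj@margMeans <- parts
  obj@dims <- stats::setNames(as.integer(dim(Xc)), c("N", "C", "D", "T"))
  obj
}

#' Correlate the top context component with active-muscle activation
#'
#' For every (context, target) condition: the mean activation of the
#' leading context-marginalization component in a peri-movement window is
#' compared with the mean envelope of the active muscle group (flexors for
#' flexion trials, extensors for extension trials) in the 420 ms
#' peri-movement window. Component activation is measured by projecting
#' the condition-averaged activity onto the component's unit population
#' pattern (its encoder axis); the demixing readout is deliberately not
#' used here because it reconstructs the target-averaged marginalization
#' and would suppress the per-target structure this comparison is about.
#' Pearson correlations are computed within each target group across
#' contexts. Warns when a group has fewer than 4 points.
#'
#' @param dpca a [DPCAResult-class] fitted on `tensor`.
#' @param tensor the [buildTrialTensor()] result the fit used.
#' @param session the session supplying EMG envelopes.
#' @param periBins half-width of the component window around the peak bin
#'   (default 10 bins = the 420 ms window).
#' @return list: `points` data.frame (context, target, component, muscle),
#'   `correlations` named by target group.
#' @export
contextComponentVsMuscle <- function(dpca, tensor, session, periBins = 10L) {
  ctxRows <- which(dpca@componentMarg == "context")
  if (!length(ctxRows)) .stopf("no context component in the dPCA fit")
  w <- dpca@encoder[, ctxRows[1]]
  w <- w / sqrt(sum(w^2))
  Xc <- .centeredAverages(tensor)
  Tn <- dim(Xc)[4]
  peakBin <- 21L                          # window is peak-aligned: 20+1+37
  binsSel <- max(1, peakBin - periBins):min(Tn, peakBin + periBins)

  emg <- gaussianSmooth(muscleActivations(session, 20L))
  gr <- muscleGroups()
  kinPeaks <- tensor$peakBins
  trCtx <- tensor$context; trTgt <- tensor$target
  trialMuscle <- vapply(seq_along(kinPeaks), function(i) {
    act <- if (trTgt[i] == "flexion") gr$flexor else gr$extensor
    mean(periMovementAverage(emg, kinPeaks[i], periBins, periBins)[act])
  }, numeric(1))

  pts <- list()
  for (ci in seq_along(tensor$contexts)) for (d in seq_along(tensor$targets)) {
    cx <- tensor$contexts[ci]; tg <- tensor$targets[d]
    comp <- mean(drop(w %*% Xc[, ci, d, binsSel]))
    mus <- mean(trialMuscle[trCtx == cx & trTgt == tg])
    pts[[length(pts) + 1L]] <- data.frame(context = cx, target = tg,
                                          component = comp, muscle = mus)
  }
  pts <- do.call(rbind, pts)
  cors <- vapply(tensor$targets, function(tg) {
    sub <- pts[pts$target == tg, ]
    if (nrow(sub) < 4)
      .warnf("contextComponentVsMuscle: only %d points for target '%s'",
             nrow(sub), tg)
    if (nrow(sub) < 2 || stats::sd(sub$component) == 0 ||
        stats::sd(sub$muscle) == 0) NA_real_
    else stats::cor(sub$component, sub$muscle)
  }, numeric(1))
  list(points = pts, correlations = cors)
}
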