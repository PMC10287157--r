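## Online neural activity patterns: a lagged 50 ms velocity readout
## trained on normal offline trials, evaluated at each online trial's peak
## movement toward the target, projected onto the target direction.

#' Fit the lagged velocity readout
#'
#' Regresses the two finger-group velocities on the current plus five most
#' recent 50 ms bins of masked channel activity, by least squares with an
#' intercept. Cross-trial leakage is prevented exactly as in
#' [buildLaggedDesign()]. Train only on normal-context offline trials.
#'
#' @param features bins x channels matrix at 50 ms.
#' @param velocities bins x 2 matrix on the same grid.
#' @param trialId per-bin trial identifier (NA bins dropped).
#' @param channelMask logical channel mask (default: all).
#' @param nHistoryBins history bins (default 5).
#' @return a [PatternReadout-class].
#' @export
fitPatternReadout <- function(features, velocities, trialId,
                              channelMask = rep(TRUE, ncol(features)),
                              nHistoryBins = 5L) {
  V <- features[, channelMask, drop = FALSE]
  lag <- buildLaggedDesign(V, trialId, nHistoryBins)
  X <- cbind(lag$X, 1)
  Y <- velocities[lag$rows, , drop = FALSE]
  Wt <- qr.coef(qr(X), Y)
  Wt[is.na(Wt)] <- 0
  obj <- new("PatternReadout")
  obj@weights <- Wt
  obj@binWidthMs <- 50L
  obj@nHistoryBins <- as.integer(nHistoryBins)
  obj@channelMask <- channelMask
  obj
}

#' Predict velocities with a pattern readout
#' @param readout a [PatternReadout-class].
#' @param features bins x channels matrix (unmasked; the readout's mask is
#'   applied).
#' @param trialId per-bin trial identifier.
#' @return list: `predicted` (rows x 2), `rows` (indices into input bins).
#' @export
predictPatternReadout <- function(readout, features, trialId) {
  V <- features[, readout@channelMask, drop = FALSE]
  lag <- buildLaggedDesign(V, trialId, readout@nHistoryBins)
  X <- cbind(lag$X, 1)
  list(predicted = X %*% readout@weights, rows = lag$rows)
}

#' Extract online neural activity patterns
#'
#' For each online trial, finds the bin with the peak decoded velocity
#' projected onto the trial's target direction (earliest bin on ties) and
#' takes the readout's velocity prediction at that bin as the trial's
#' neural activity pattern. The pushing magnitude is the pattern's scalar
#' projection onto the target direction.
#'
#' @param readout a [PatternReadout-class].
#' @param run a [simulateClosedLoop()] result (features at the decoder
#'   rate are rebinned to the readout's 50 ms grid by averaging).
#' @param decoderBinMs bin width of the run's features (default 32).
#' @param startPos session start position for the first trial (default
#'   center).
#' @return data.frame: trial, context, flexion, pattern velocities
#'   (`vel_index`, `vel_mrs`), `pushing_magnitude`, target direction
#'   components.
#' @export
extractPatterns <- function(readout, run, decoderBinMs = 32L,
                            startPos = c(50, 50)) {
  nTrials <- length(run$targets)
  out <- list()
  prevEnd <- startPos
  for (i in seq_len(nTrials)) {
    feats <- run$features[[i]]
    vels <- run$velocities[[i]]
    start <- prevEnd
    tgt <- run$targets[[i]]
    prevEnd <- run$trajectories[[i]][nrow(run$trajectories[[i]]), ]
    # rebin decoder-rate bins to the readout grid
    k <- max(1L, round(readout@binWidthMs / decoderBinMs))
    f50 <- .binRows(feats, k)
    v50 <- .binRows(vels, k)
    if (nrow(f50) <= readout@nHistoryBins) {
      .warnf("extractPatterns: trial %d has too few bins, skipped", i)
      next
    }
    dirv <- tgt - start
    nd <- sqrt(sum(dirv^2))
    if (nd == 0) next      # no defined target direction (repeated center)
    dirv <- dirv / nd
    pred <- predictPatternReadout(readout, f50, rep(i, nrow(f50)))
    proj <- drop(v50[pred$rows, , drop = FALSE] %*% dirv)
    best <- which.max(proj)           # earliest max on ties
    pat <- pred$predicted[best, ]
    out[[length(out) + 1L]] <- data.frame(
      trial = i, context = run$contexts[i],
      flexion = mean(tgt) > mean(start),
      vel_index = pat[1], vel_mrs = pat[2],
      dir_index = dirv[1], dir_mrs = dirv[2],
      pushing_magnitude = sum(pat * dirv))
  }
  do.call(rbind, out)
}

#' Pushing magnitude of a pattern
#'
#' Scalar projection of a velocity pattern onto a unit target direction.
#'
#' @param pattern length-2 velocity vector.
#' @param targetDirection length-2 unit vector.
#' @return scalar.
#' @export
pushingMagnitude <- function(pattern, targetDirection) {
  nd <- sqrt(sum(targetDirection^2))
  if (abs(nd - 1) > 1e-6)
    .stopf("pushingMagnitude: target direction must be a unit vector")
  sum(pattern * targetDirection)
}

#' Compare pushing magnitudes between contexts per movement group
#'
#' Splits patterns into flexion, extension, and (2-DOF) split-movement
#' groups, runs a two-sample t-test of normal versus off-context pushing
#' magnitudes per group, and applies Benjamini-Hochberg FDR at 5% across
#' the groups of a session. Groups with fewer than 2 trials on either side
#' are skipped with a warning.
#'
#' @param patterns data.frame from [extractPatterns()].
#' @param fdrLevel FDR level (default 0.05).
#' @return data.frame: group, delta (off - normal), t, p, p_adj,
#'   significant.
#' @export
comparePatternGroups <- function(patterns, fdrLevel = 0.05) {
  patterns$group <- ifelse(patterns$flexion, "flexion", "extension")
  rows <- list()
  for (g in unique(patterns$group)) {
    sub <- patterns[patterns$group == g, ]
    a <- sub$pushing_magnitude[sub$context == "normal"]
    b <- sub$pushing_magnitude[sub$context != "normal"]
    if (length(a) < 2 || length(b) < 2) {
      .warnf("comparePatternGroups: group '%s' has too few trials, skipped", g)
      next
    }
    tt <- compareGroups(b, a, kind = "two_sample_t", ciLevel = 0.95)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, delta = mean(b) - mean(a), t = tt$statistic, p = tt$p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("comparePatternGroups: no comparable group")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdrLevel
  out
}
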