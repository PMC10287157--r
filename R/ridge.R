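## Lagged ridge regression from SBP to kinematics or muscle activation,
## with cross-context generalization testing.

#' Build a lagged design matrix
#'
#' Row `t` concatenates the feature bins `t, t-1, ..., t-nHistory` for
#' every masked-in channel. Lagging never crosses trial boundaries: the
#' first `nHistory` bins of each trial are dropped, and trials shorter
#' than the history are skipped with a warning.
#'
#' @param values bins x channels feature matrix.
#' @param trialId per-bin trial identifier (NA = idle bins, dropped).
#' @param nHistoryBins bins of history (default 12).
#' @return list: `X` (rows x (channels * (nHistory+1)) design, no
#'   intercept column), `rows` (indices into the input rows).
#' @export
buildLaggedDesign <- function(values, trialId, nHistoryBins = 12L) {
  nHistoryBins <- as.integer(nHistoryBins)
  keepRows <- integer(0)
  for (tid in unique(trialId[!is.na(trialId)])) {
    rows <- which(!is.na(trialId) & trialId == tid)
    if (length(rows) <= nHistoryBins) {
      .warnf("buildLaggedDesign: trial %s shorter than history, skipped", tid)
      next
    }
    keepRows <- c(keepRows, if (nHistoryBins > 0)
      rows[-seq_len(nHistoryBins)] else rows)
  }
  nc <- ncol(values)
  X <- matrix(0, length(keepRows), nc * (nHistoryBins + 1L))
  for (h in 0:nHistoryBins)
    X[, h * nc + seq_len(nc)] <- values[keepRows - h, , drop = FALSE]
  list(X = X, rows = keepRows)
}

#' Fit ridge regression with an unpenalized intercept
#'
#' Solves the penalized normal equations on centered data so the intercept
#' is never shrunk. `lambda = 0` reproduces ordinary least squares (a rank
#' error advises a positive penalty when the system is singular).
#'
#' @param X rows x features design (no intercept column).
#' @param Y rows x outputs targets.
#' @param lambda nonnegative ridge penalty.
#' @param center,scale standardization vectors for the columns of `X`
#'   (training-fold statistics); computed from `X` when NULL.
#' @return list: `weights` ((features + 1) x outputs, intercept last),
#'   `center`, `scale`.
#' @export
fitRidge <- function(X, Y, lambda = 0, center = NULL, scale = NULL) {
  stopifnot(nrow(X) == NROW(Y), lambda >= 0)
  Y <- as.matrix(Y)
  if (lambda == 0 && nrow(X) <= ncol(X))
    .stopf("fitRidge: singular system at lambda = 0; use lambda > 0")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  A <- crossprod(Xs) + diag(lambda, ncol(Xs))
  R <- tryCatch(chol(A), error = function(e)
    .stopf("fitRidge: singular system at lambda = %g; use lambda > 0", lambda))
  B <- backsolve(R, backsolve(R, crossprod(Xs, Yc), transpose = TRUE))
  Braw <- B / scale
  intercept <- ym - drop(crossprod(Braw, center))
  list(weights = rbind(Braw, intercept), center = center, scale = scale)
}

#' Predict from a fitted ridge weight matrix
#' @param weights (features + 1) x outputs matrix, intercept last.
#' @param X rows x features design.
#' @return rows x outputs predictions.
#' @export
predictRidge <- function(weights, X) {
  nf <- nrow(weights) - 1L
  stopifnot(ncol(X) == nf)
  sweep(X %*% weights[seq_len(nf), , drop = FALSE], 2,
        weights[nf + 1L, ], "+")
}

#' Prediction accuracy metrics
#'
#' Pearson correlation and normalized mean squared error (MSE divided by
#' the variance of the measured data, i.e. the fraction of unexplained
#' variance: the constant-mean predictor scores exactly 1) per output
#' column. The denominator is always the test set's own variance.
#'
#' @param predicted,measured equal-shape matrices (or vectors).
#' @return data.frame with columns `output`, `r`, `nmse`, and attribute-free
#'   column `n` (samples).
#' @export
predictionMetrics <- function(predicted, measured) {
  predicted <- as.matrix(predicted); measured <- as.matrix(measured)
  stopifnot(dim(predicted) == dim(measured), nrow(measured) >= 2)
  outs <- colnames(measured)
  if (is.null(outs)) outs <- paste0("y", seq_len(ncol(measured)))
  res <- lapply(seq_len(ncol(measured)), function(j) {
    m <- measured[, j]; p <- predicted[, j]
    v <- mean((m - mean(m))^2)
    if (v == 0) .stopf("predictionMetrics: zero variance in measured output %s",
                       outs[j])
    data.frame(output = outs[j],
               r = if (stats::sd(p) == 0) 0 else stats::cor(p, m),
               nmse = mean((m - p)^2) / v,
               n = length(m))
  })
  do.call(rbind, res)
}

# Generalized cross-validation choice of lambda on a training design.
.gcvLambda <- function(X, Y, grid = 10^seq(-2, 4, length.out = 13)) {
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  sv <- svd(Xs, nu = 0, nv = 0)$d
  Yc <- scale(as.matrix(Y), scale = FALSE)
  n <- nrow(Xs)
  # GCV via the SVD: df(lambda) = sum d_i^2/(d_i^2+lambda)
  s <- svd(Xs)
  UtY <- crossprod(s$u, Yc)
  score <- vapply(grid, function(lam) {
    shrink <- s$d^2 / (s$d^2 + lam)
    df <- sum(shrink)
    fit <- s$u %*% (UtY * shrink)
    rss <- sum((Yc - fit)^2)
    rss / (n * (1 - df / n)^2)
  }, numeric(1))
  grid[which.min(score)]
}

#' Cross-context generalization of offline decoding
#'
#' Implements the 10-fold cross-context protocol: SBP is binned at 32 ms,
#' channels masked to mean TCFR > 1 Hz, 12 bins of history appended, and a
#' ridge model trained on nine folds of normal trials is tested on the
#' held-out normal fold and on all off-context bins. Folds split at trial
#' boundaries with bin counts as equal as trial granularity allows.
#' Features are standardized with training-fold statistics only.
#'
#' @param session a [SessionRecord-class].
#' @param target `"emg_envelope"` (muscle activations) or `"kinematics"`
#'   (position and velocity of both finger groups, fitted jointly).
#' @param testContexts contexts to generalize to (default: all non-normal
#'   contexts present).
#' @param ridgeLambda fixed penalty, or NULL for generalized
#'   cross-validation on the training data.
#' @param folds number of folds (default 10).
#' @param binWidthMs,nHistoryBins protocol parameters (32 ms, 12 bins).
#' @param tcfrMaskHz channel mask threshold (default 1 Hz).
#' @return list: `perFold` data.frame of metrics (fold x test set x
#'   output), `summary` mean +/- sd per test set and output,
#'   `percentChange` off-context vs held-out normal, `lambda`, `mask`.
#' @export
crossvalGeneralization <- function(session,
                                   target = c("emg_envelope", "kinematics"),
                                   testContexts = NULL, ridgeLambda = NULL,
                                   folds = 10L, binWidthMs = 32L,
                                   nHistoryBins = 12L, tcfrMaskHz = 1) {
  target <- match.arg(target)
  st <- streams(session)
  tr <- selectAnalysisTrials(session)
  if (is.null(testContexts))
    testContexts <- setdiff(unique(tr$context), "normal")

  sbp <- binSBP(st, binWidthMs)
  tc <- binTCFR(st@crossingTimes, binWidthMs, nrow(st@sbp1ms),
                originMs = st@originMs)
  mask <- colMeans(featureValues(tc)) > tcfrMaskHz
  if (!any(mask)) .stopf("crossvalGeneralization: no channel passes the mask")
  V <- featureValues(sbp)[, mask, drop = FALSE]

  Yb <- if (target == "emg_envelope") {
    featureValues(muscleActivations(session, binWidthMs))
  } else {
    kin <- savgolKinematics32(st, binWidthMs)
    kin
  }
  nB <- min(nrow(V), nrow(Yb))
  V <- V[seq_len(nB), , drop = FALSE]
  Yb <- Yb[seq_len(nB), , drop = FALSE]

  binTrial <- .assignBinsToTrials(binStartTimes(sbp)[seq_len(nB)], tr)
  lag <- buildLaggedDesign(V, binTrial, nHistoryBins)
  X <- lag$X
  Y <- Yb[lag$rows, , drop = FALSE]
  trialOfRow <- binTrial[lag$rows]
  ctxOfRow <- tr$context[trialOfRow]

  normTrials <- which(tr$context == "normal")
  if (length(normTrials) < folds)
    .stopf("crossvalGeneralization: fewer than %d normal trials", folds)
  foldOf <- .assignFolds(trialOfRow, normTrials, folds)

  perFold <- list()
  lambdas <- numeric(folds)
  for (f in seq_len(folds)) {
    trainRows <- which(ctxOfRow == "normal" & foldOf != f)
    testRows <- which(ctxOfRow == "normal" & foldOf == f)
    lam <- if (is.null(ridgeLambda))
      .gcvLambda(X[trainRows, , drop = FALSE], Y[trainRows, , drop = FALSE])
    else ridgeLambda
    lambdas[f] <- lam
    fit <- fitRidge(X[trainRows, , drop = FALSE],
                    Y[trainRows, , drop = FALSE], lam)
    evalSet <- function(rows, label) {
      if (!length(rows)) return(NULL)
      m <- predictionMetrics(predictRidge(fit$weights,
                                          X[rows, , drop = FALSE]),
                             Y[rows, , drop = FALSE])
      cbind(fold = f, test_set = label, m)
    }
    out <- list(evalSet(testRows, "normal_heldout"))
    for (cx in testContexts)
      out <- c(out, list(evalSet(which(ctxOfRow == cx), cx)))
    perFold[[f]] <- do.call(rbind, out)
  }
  perFold <- do.call(rbind, perFold)

  summary <- stats::aggregate(cbind(r, nmse) ~ test_set + output,
                              data = perFold, FUN = mean)
  sds <- stats::aggregate(cbind(r, nmse) ~ test_set + output,
                          data = perFold, FUN = stats::sd)
  names(sds)[3:4] <- c("r_sd", "nmse_sd")
  summary <- merge(summary, sds)

  pc <- NULL
  base <- summary[summary$test_set == "normal_heldout", ]
  for (cx in intersect(testContexts, unique(perFold$test_set))) {
    off <- summary[summary$test_set == cx, ]
    m <- merge(base, off, by = "output", suffixes = c("_normal", "_off"))
    pc <- rbind(pc, data.frame(
      context = cx, output = m$output,
      nmse_pct_change = 100 * (m$nmse_off - m$nmse_normal) / m$nmse_normal,
      r_pct_change = 100 * (m$r_off - m$r_normal) / abs(m$r_normal)))
  }
  list(perFold = perFold, summary = summary, percentChange = pc,
       lambda = lambdas, mask = mask, target = target)
}

# 32 ms kinematics: positions averaged per bin, velocities from the
# Savitzky-Golay 20 ms pipeline resampled by linear interpolation.
savgolKinematics32 <- function(st, binWidthMs) {
  kin20 <- savgolVelocity(st@fingerPosition, originMs = st@originMs)
  pos <- .binRows(st@fingerPosition, binWidthMs, FUN = "mean")
  t32 <- st@originMs + (seq_len(nrow(pos)) - 0.5) * binWidthMs
  t20 <- binStartTimes(kin20$velocity) + 10
  vel <- apply(featureValues(kin20$velocity), 2, function(v)
    stats::approx(t20, v, xout = t32, rule = 2)$y)
  out <- cbind(pos, matrix(vel, nrow(pos)))
  colnames(out) <- c("pos_index", "pos_mrs", "vel_index", "vel_mrs")
  out
}

# Contiguous-trial fold assignment balancing bins per fold.
.assignFolds <- function(trialOfRow, normTrials, folds) {
  binsPerTrial <- table(factor(trialOfRow, levels = normTrials))
  cum <- cumsum(as.numeric(binsPerTrial))
  total <- cum[length(cum)]
  foldOfTrial <- pmin(folds, ceiling(cum / total * folds))
  names(foldOfTrial) <- names(binsPerTrial)
  out <- rep(NA_integer_, length(trialOfRow))
  m <- match(as.character(trialOfRow), names(foldOfTrial))
  out[!is.na(m)] <- foldOfTrial[m[!is.na(m)]]
  out
}

#' Off-context amplitude recovery of a normal-trained decoder
#'
#' Trains a ridge decoder for flexor-muscle activation on all normal
#' trials, predicts the off-context trials, and compares the peri-movement
#' amplitude (flexion-trial window mean minus extension-trial window mean,
#' which removes the shared baseline) of predictions versus measurements.
#' When the off-context flexor gain is `g`, a decoder blind to the context
#' shift under-predicts by about a factor `1/g`, so
#' `ratio * g` is close to 1.
#'
#' @param session a [SessionRecord-class] with EMG.
#' @param context off-context label to evaluate (default "spring").
#' @param ridgeLambda ridge penalty (default 10).
#' @param binWidthMs,nHistoryBins protocol parameters.
#' @return list: `ratio` (predicted/measured amplitude), `predictedAmp`,
#'   `measuredAmp`.
#' @export
decoderAmplitudeRatio <- function(session, context = "spring",
                                  ridgeLambda = 10, binWidthMs = 32L,
                                  nHistoryBins = 12L) {
  st <- streams(session)
  tr <- selectAnalysisTrials(session)
  sbp <- binSBP(st, binWidthMs)
  tc <- binTCFR(st@crossingTimes, binWidthMs, nrow(st@sbp1ms),
                originMs = st@originMs)
  mask <- colMeans(featureValues(tc)) > 1
  V <- featureValues(sbp)[, mask, drop = FALSE]
  emg <- featureValues(muscleActivations(session, binWidthMs))
  flex <- muscleGroups()$flexor
  Y <- rowMeans(emg[, flex, drop = FALSE])
  nB <- min(nrow(V), length(Y))
  binTrial <- .assignBinsToTrials(binStartTimes(sbp)[seq_len(nB)], tr)
  lag <- buildLaggedDesign(V[seq_len(nB), , drop = FALSE], binTrial,
                           nHistoryBins)
  X <- lag$X
  y <- Y[lag$rows]
  ctx <- tr$context[binTrial[lag$rows]]
  fit <- fitRidge(X[ctx == "normal", , drop = FALSE], y[ctx == "normal"],
                  ridgeLambda)
  pred <- drop(predictRidge(fit$weights, X))

  kin <- savgolVelocity(st@fingerPosition, originMs = st@originMs)
  win <- .periWindowMeans(tr, kin, lag$rows, binStartTimes(sbp), binWidthMs)
  periMean <- function(vals, rowsSel) {
    keep <- win$trialRows[win$context == context & win$flexion == rowsSel]
    mean(vals[unlist(keep)], na.rm = TRUE)
  }
  measuredAmp <- periMean(y, TRUE) - periMean(y, FALSE)
  predictedAmp <- periMean(pred, TRUE) - periMean(pred, FALSE)
  list(ratio = predictedAmp / measuredAmp, predictedAmp = predictedAmp,
       measuredAmp = measuredAmp)
}

# For each out-target trial: design-row indices inside the 420 ms
# peri-movement window, with context and movement direction.
.periWindowMeans <- function(tr, kin, lagRows, binStarts, binWidthMs) {
  out <- list(trialRows = list(), context = character(0), flexion = logical(0))
  rowTime <- binStarts[lagRows]
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$target_center_index[i] == 50) next
    pk <- findPeakMovement(kin$velocity, tr$presentation_time_ms[i],
                           tr$end_time_ms[i])
    lo <- pk$peakTimeMs - 10 * 20; hi <- pk$peakTimeMs + 10 * 20
    rows <- which(rowTime >= lo & rowTime <= hi)
    if (!length(rows)) next
    k <- k + 1L
    out$trialRows[[k]] <- rows
    out$context[k] <- tr$context[i]
    out$flexion[k] <- tr$target_center_index[i] > 50
  }
  out
}
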