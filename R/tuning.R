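## Per-channel tuning and context-modulation regression.
##
## For channel n, the standardized feature series x̂ and its product with a
## context indicator c (1 = off-context) form the design [x̂, c*x̂]; finger
## position and velocity are regressed on it column-wise with an intercept.
## A channel is "tuned" when either first-row coefficient survives FDR, and
## "context modulated" when either second-row (indicator) coefficient does.

#' Optimal feature lag against kinematics
#'
#' Shifts a channel's 20 ms binned feature over a symmetric lag range and
#' returns the lag maximizing the L2 norm of the ordinary-least-squares
#' coefficients from the feature to finger position and velocity. Ties are
#' broken toward the smallest absolute lag, negative first. Positive lag
#' means the feature leads the kinematics.
#'
#' @param feature numeric vector of binned channel activity.
#' @param kinematics bins x 2 matrix (position, velocity).
#' @param lagRangeBins maximum absolute lag in bins (default 10).
#' @return integer lag (bins).
#' @export
optimalLag <- function(feature, kinematics, lagRangeBins = 10L) {
  if (stats::sd(feature) == 0) {
    .warnf("optimalLag: constant feature, coefficients are zero; lag 0")
    return(0L)
  }
  lags <- seq(-lagRangeBins, lagRangeBins)
  n <- length(feature)
  norms <- vapply(lags, function(L) {
    if (L >= 0) { f <- feature[seq_len(n - L)]
                  k <- kinematics[seq.int(L + 1, n), , drop = FALSE] }
    else { f <- feature[seq.int(-L + 1, n)]
           k <- kinematics[seq_len(n + L), , drop = FALSE] }
    f <- f - mean(f)
    b <- crossprod(k - rep(colMeans(k), each = nrow(k)), f) / sum(f^2)
    sqrt(sum(b^2))
  }, numeric(1))
  # ties: smallest |lag|, then negative before positive
  ord <- order(-norms, abs(lags), lags)
  as.integer(lags[ord[1]])
}

#' Context-modulated tuning regression for one channel
#'
#' Fits `Y = B + [x̂, c x̂] W` column-wise by least squares, where `x̂` is
#' the standardized channel feature, `c` the off-context indicator, and
#' `Y` holds finger position and velocity. Returns per-coefficient
#' estimates, standard errors, t statistics and two-sided p values
#' (residual-based, T - 3 degrees of freedom per regression).
#'
#' @param xhat standardized feature series (mean 0, sd 1 over the
#'   concatenated normal + off-context data).
#' @param context 0/1 indicator (1 = off-context sample).
#' @param Y bins x 2 kinematics matrix (position, velocity).
#' @return data.frame with columns `row` ("feature" or "feature_x_context"),
#'   `output` ("position" or "velocity"), `estimate`, `se`, `t`, `p`.
#' @export
contextTuningRegression <- function(xhat, context, Y) {
  n <- length(xhat)
  if (n <= 4) .stopf("contextTuningRegression: need more than 4 samples")
  if (all(context == 0)) {
    # c identically zero: the indicator column is analytically zero, so
    # the fit reduces exactly to the simple regression Y = B + xhat w
    X <- cbind(1, xhat)
    XtX <- crossprod(X)
    R <- chol(XtX)
    coef <- backsolve(R, backsolve(R, crossprod(X, Y), transpose = TRUE))
    resid <- Y - X %*% coef
    df <- n - 2L
    sigma2 <- colSums(resid^2) / df
    XtXinv_diag <- diag(chol2inv(R))
    out <- expand.grid(row = c("intercept", "feature"),
                       output = c("position", "velocity"),
                       stringsAsFactors = FALSE)
    out$estimate <- as.numeric(coef)
    out$se <- sqrt(rep(XtXinv_diag, 2) * rep(sigma2, each = 2))
    out$t <- out$estimate / out$se
    out$p <- 2 * stats::pt(-abs(out$t), df)
    return(out[out$row != "intercept", , drop = FALSE])
  }
  if (length(unique(context)) < 2)
    .stopf("contextTuningRegression: both contexts must be present (rank deficiency)")
  X <- cbind(1, xhat, context * xhat)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e)
    .stopf("contextTuningRegression: rank-deficient design"))
  coef <- backsolve(R, backsolve(R, crossprod(X, Y), transpose = TRUE))
  resid <- Y - X %*% coef
  df <- n - 3L
  sigma2 <- colSums(resid^2) / df
  XtXinv_diag <- diag(chol2inv(R))
  out <- expand.grid(row = c("intercept", "feature", "feature_x_context"),
                     output = c("position", "velocity"),
                     stringsAsFactors = FALSE)
  out$estimate <- as.numeric(coef)
  out$se <- sqrt(rep(XtXinv_diag, 2) * rep(sigma2, each = 3))
  out$t <- out$estimate / out$se
  out$p <- 2 * stats::pt(-abs(out$t), df)
  out[out$row != "intercept", , drop = FALSE]
}

#' Classify channels as tuned / context-modulated
#'
#' Applies Benjamini-Hochberg correction at `fdrLevel` (default 0.1%)
#' separately to the tuning (feature) and context-modulation
#' (feature-by-context) coefficient families of a session. A channel is
#' tuned when either feature coefficient survives and context-modulated
#' when either feature-by-context coefficient survives; summary
#' percentages of context modulation are computed among tuned channels.
#' Pooling every coefficient into one family is available via
#' `family = "pooled"`, but note it is anti-conservative for the
#' modulation calls: the overwhelmingly significant tuning p-values raise
#' the BH threshold the modulation coefficients are then judged against.
#'
#' @param fits list of per-channel data.frames from
#'   [contextTuningRegression()].
#' @param fdrLevel FDR level (default 0.001).
#' @param family `"per_row"` (tuning and modulation families corrected
#'   separately, default) or `"pooled"` (all coefficients in one family).
#' @return list: `perChannel` data.frame (channel, tuned,
#'   context_modulated), `nTuned`, `nModulated`,
#'   `pctModulatedAmongTuned`.
#' @export
classifyChannels <- function(fits, fdrLevel = 0.001,
                             family = c("per_row", "pooled")) {
  family <- match.arg(family)
  if (!length(fits))
    return(list(perChannel = data.frame(channel = integer(0),
                                        tuned = logical(0),
                                        context_modulated = logical(0)),
                nTuned = 0L, nModulated = 0L,
                pctModulatedAmongTuned = NaN))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i)
    cbind(channel = i, fits[[i]])))
  if (family == "pooled") {
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  } else {
    tab$p_adj <- NA_real_
    for (r in unique(tab$row))
      tab$p_adj[tab$row == r] <- stats::p.adjust(tab$p[tab$row == r],
                                                 method = "BH")
  }
  sig <- tab$p_adj < fdrLevel
  perChannel <- data.frame(
    channel = seq_along(fits),
    tuned = vapply(seq_along(fits), function(i)
      any(sig[tab$channel == i & tab$row == "feature"]), logical(1)),
    context_modulated = vapply(seq_along(fits), function(i)
      any(sig[tab$channel == i & tab$row == "feature_x_context"]),
      logical(1)))
  nTuned <- sum(perChannel$tuned)
  nMod <- sum(perChannel$tuned & perChannel$context_modulated)
  list(perChannel = perChannel, nTuned = nTuned, nModulated = nMod,
       pctModulatedAmongTuned = if (nTuned) 100 * nMod / nTuned else NaN,
       coefficients = tab)
}

#' Session-level tuning and context-modulation analysis
#'
#' Runs the full per-channel pipeline on a session: selects analysis
#' trials, bins the chosen feature and kinematics at 20 ms, concatenates
#' normal and off-context trial bins, standardizes each channel over the
#' concatenated data, finds the optimal lag per channel, fits the
#' context-indicator regression, and applies session-wide FDR.
#' The index finger trace provides the kinematics (1-DOF convention).
#'
#' @param session a [SessionRecord-class] with normal plus exactly one or
#'   more off-context trial sets.
#' @param feature `"sbp"` or `"tcfr"`.
#' @param offContext which context counts as off-context (default: every
#'   non-normal context present).
#' @param fdrLevel FDR level (default 0.001).
#' @param lagRangeBins lag search range (default 10).
#' @param lagOn fit the optimal lag on `"concatenated"` (default) or
#'   `"normal"` data only.
#' @param family FDR family passed to [classifyChannels()].
#' @return the [classifyChannels()] result plus `lags` and `feature`.
#' @export
tuningAnalysis <- function(session, feature = c("sbp", "tcfr"),
                           offContext = NULL, fdrLevel = 0.001,
                           lagRangeBins = 10L,
                           lagOn = c("concatenated", "normal"),
                           family = c("per_row", "pooled")) {
  feature <- match.arg(feature)
  lagOn <- match.arg(lagOn)
  st <- streams(session)
  tr <- selectAnalysisTrials(session)
  if (is.null(offContext))
    offContext <- setdiff(unique(tr$context), "normal")
  tr <- tr[tr$context %in% c("normal", offContext), , drop = FALSE]
  if (!nrow(tr) || !any(tr$context == "normal") ||
      !any(tr$context != "normal"))
    .stopf("tuningAnalysis: need normal and off-context trials")

  feats <- if (feature == "sbp") binSBP(st, 20L)
  else binTCFR(removeArtifacts(st@crossingTimes), 20L, nrow(st@sbp1ms),
               originMs = st@originMs)
  kin <- savgolVelocity(st@fingerPosition, originMs = st@originMs)

  starts <- binStartTimes(feats)
  binTrial <- .assignBinsToTrials(starts, tr)
  keep <- !is.na(binTrial)
  idx <- which(keep)
  ctxBin <- as.integer(tr$context[binTrial[keep]] != "normal")

  Xall <- featureValues(feats)[idx, , drop = FALSE]
  nB <- min(nrow(Xall), nrow(featureValues(kin$position)))
  Y <- cbind(position = featureValues(kin$position)[idx, 1],
             velocity = featureValues(kin$velocity)[idx, 1])

  fits <- vector("list", ncol(Xall))
  lags <- integer(ncol(Xall))
  for (ch in seq_len(ncol(Xall))) {
    x <- Xall[, ch]
    if (stats::sd(x) == 0) {
      lags[ch] <- 0L
      fits[[ch]] <- data.frame(row = c("feature", "feature_x_context"),
                               output = "velocity", estimate = 0, se = Inf,
                               t = 0, p = 1)[rep(1:2, 2), ]
      next
    }
    xs <- (x - mean(x)) / stats::sd(x)
    lagIdx <- if (lagOn == "normal") which(ctxBin == 0) else seq_along(xs)
    lags[ch] <- optimalLag(xs[lagIdx], Y[lagIdx, , drop = FALSE],
                           lagRangeBins)
    L <- lags[ch]
    n <- length(xs)
    if (L >= 0) { sel_x <- seq_len(n - L); sel_y <- seq.int(L + 1, n) }
    else { sel_x <- seq.int(-L + 1, n); sel_y <- seq_len(n + L) }
    fits[[ch]] <- contextTuningRegression(xs[sel_x], ctxBin[sel_y],
                                          Y[sel_y, , drop = FALSE])
  }
  res <- classifyChannels(fits, fdrLevel, family = match.arg(family))
  res$lags <- lags
  res$feature <- feature
  res
}

# Map each bin start time to the trial covering it (NA when idle).
.assignBinsToTrials <- function(binStarts, trialsDf) {
  iv <- findInterval(binStarts, trialsDf$presentation_time_ms)
  ok <- iv >= 1 & binStarts < trialsDf$end_time_ms[pmax(iv, 1)]
  out <- rep(NA_integer_, length(binStarts))
  out[ok] <- iv[ok]
  out
}
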