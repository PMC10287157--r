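## Feature extraction and behavioral-signal conditioning.

.checkBinWidth <- function(binWidthMs)
  if (!binWidthMs %in% c(20L, 32L, 50L))
    .stopf("bin width must be 20, 32, or 50 ms (got %s)", binWidthMs)

#' Bin spiking band power
#'
#' Each bin value is the sum of the per-ms rectified sums over the bin
#' divided by the total number of raw 2 kHz samples in the bin. Bins are
#' contiguous, non-overlapping, half-open; a trailing partial bin is
#' discarded. A bin with zero raw samples yields 0 with a warning.
#'
#' @param streams a [ContinuousStreams-class] object.
#' @param binWidthMs 20, 32, or 50.
#' @return a [BinnedFeatures-class] of kind `"sbp"`.
#' @export
binSBP <- function(streams, binWidthMs = 32L) {
  binWidthMs <- as.integer(binWidthMs)
  .checkBinWidth(binWidthMs)
  nMs <- nrow(streams@sbp1ms)
  if (nMs < binWidthMs) .stopf("binSBP: stream shorter than one bin")
  sums <- .binRows(streams@sbp1ms, binWidthMs, FUN = "sum")
  counts <- .binRows(streams@rawSampleCount1ms + 0, binWidthMs, FUN = "sum")
  if (any(counts == 0)) {
    .warnf("binSBP: %d bin/channel cells had zero raw samples; set to 0",
           sum(counts == 0))
    counts[counts == 0] <- Inf
  }
  values <- sums / counts
  nBins <- nrow(values)
  new("BinnedFeatures", values = values, binWidthMs = binWidthMs,
      binStartTimesMs = streams@originMs + (seq_len(nBins) - 1) * binWidthMs,
      channelMask = rep(TRUE, ncol(values)), featureKind = "sbp")
}

#' Bin threshold-crossing firing rate
#'
#' Counts events per half-open bin and divides by the bin width, giving a
#' rate in Hz.
#'
#' @param crossings per-channel list of sorted event times (ms), relative
#'   to `originMs`.
#' @param binWidthMs 20, 32, or 50.
#' @param durationMs stream duration in ms (trailing partial bin dropped).
#' @param originMs clock offset of the bins.
#' @return a [BinnedFeatures-class] of kind `"tcfr"` (Hz).
#' @export
binTCFR <- function(crossings, binWidthMs, durationMs, originMs = 0L) {
  binWidthMs <- as.integer(binWidthMs)
  .checkBinWidth(binWidthMs)
  nBins <- durationMs %/% binWidthMs
  values <- matrix(0, nBins, length(crossings))
  edges <- (0:nBins) * binWidthMs
  for (ch in seq_along(crossings)) {
    ct <- crossings[[ch]]
    ct <- ct[ct >= 0 & ct < nBins * binWidthMs]
    if (length(ct))
      values[, ch] <- tabulate(findInterval(ct, edges, left.open = FALSE),
                               nbins = nBins)
  }
  values <- values / (binWidthMs / 1000)   # Hz
  new("BinnedFeatures", values = values, binWidthMs = binWidthMs,
      binStartTimesMs = originMs + (seq_len(nBins) - 1) * binWidthMs,
      channelMask = rep(TRUE, ncol(values)), featureKind = "tcfr")
}

#' Remove cross-channel coincidence artifacts from crossing times
#'
#' For every 1 ms tick in which `threshold` or more channels have a
#' threshold crossing, all events at that tick are removed on all
#' channels. Idempotent.
#'
#' @param crossings per-channel list of event times (ms).
#' @param threshold minimum number of coincident channels (default 20).
#' @return cleaned per-channel list.
#' @export
removeArtifacts <- function(crossings, threshold = 20L) {
  ticks <- lapply(crossings, function(ct) unique(floor(ct)))
  tab <- table(unlist(ticks, use.names = FALSE))
  bad <- as.numeric(names(tab)[tab >= threshold])
  if (!length(bad)) return(crossings)
  lapply(crossings, function(ct) ct[!(floor(ct) %in% bad)])
}

#' Muscle-activation envelope from raw EMG
#'
#' Applies a causal second-order Butterworth band-pass (100-500 Hz) to
#' each 10 kHz EMG channel and takes the mean absolute value of the
#' filtered signal in every binning period.
#'
#' @param emg time x channel matrix of raw EMG at `rateHz`.
#' @param binWidthMs 20, 32, or 50.
#' @param rateHz sampling rate (must be 10000).
#' @param zeroPhase apply the filter forward-backward instead of causally
#'   (off by default, matching online acquisition).
#' @return a [BinnedFeatures-class] of kind `"emg_envelope"`.
#' @export
emgEnvelope <- function(emg, binWidthMs = 32L, rateHz = 10000,
                        zeroPhase = FALSE) {
  binWidthMs <- as.integer(binWidthMs)
  .checkBinWidth(binWidthMs)
  if (rateHz != 10000)
    .stopf("emgEnvelope expects 10 kHz raw EMG (got %g Hz)", rateHz)
  samplesPerBin <- binWidthMs * 10L
  if (nrow(emg) < max(samplesPerBin, 50L))
    .stopf("emgEnvelope: stream shorter than the filter warm-up")
  bf <- signal::butter(2, c(100, 500) / (rateHz / 2), type = "pass")
  filt <- apply(emg, 2, function(x)
    if (zeroPhase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x)))
  values <- .binRows(abs(filt), samplesPerBin, FUN = "mean")
  new("BinnedFeatures", values = values, binWidthMs = binWidthMs,
      binStartTimesMs = (seq_len(nrow(values)) - 1) * binWidthMs,
      channelMask = rep(TRUE, ncol(values)), featureKind = "emg_envelope")
}

#' Binned muscle activation of a session
#'
#' Convenience wrapper that yields muscle-activation envelopes on a bin
#' grid whichever way the session stores EMG: raw 10 kHz EMG is passed
#' through [emgEnvelope()], envelope-resolution (1 kHz) EMG is averaged
#' per bin.
#'
#' @param session a [SessionRecord-class].
#' @param binWidthMs 20, 32, or 50.
#' @return a [BinnedFeatures-class] of kind `"emg_envelope"`.
#' @export
muscleActivations <- function(session, binWidthMs = 32L) {
  st <- streams(session)
  if (!length(st@emg)) .stopf("session has no EMG stream")
  if (st@emgRateHz == 10000)
    return(emgEnvelope(st@emg, binWidthMs, rateHz = 10000))
  binWidthMs <- as.integer(binWidthMs)
  .checkBinWidth(binWidthMs)
  values <- .binRows(st@emg, binWidthMs, FUN = "mean")
  new("BinnedFeatures", values = values, binWidthMs = binWidthMs,
      binStartTimesMs = st@originMs + (seq_len(nrow(values)) - 1) * binWidthMs,
      channelMask = rep(TRUE, ncol(values)), featureKind = "emg_envelope")
}

#' Gaussian smoothing of binned features
#'
#' Convolves each channel with a unit-sum Gaussian kernel. "100 ms" is
#' read as the kernel's standard deviation by default (the FWHM reading is
#' available via `interpretation`); the kernel is truncated at +/- 3 sigma
#' and renormalized at the edges so constants are preserved everywhere.
#'
#' @param binned a [BinnedFeatures-class] on a 20 ms grid.
#' @param kernelMs kernel width in ms (default 100).
#' @param interpretation `"sd"` (default) or `"fwhm"`.
#' @return smoothed [BinnedFeatures-class].
#' @export
gaussianSmooth <- function(binned, kernelMs = 100,
                           interpretation = c("sd", "fwhm")) {
  interpretation <- match.arg(interpretation)
  sigmaBins <- kernelMs / binned@binWidthMs
  if (interpretation == "fwhm") sigmaBins <- sigmaBins / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigmaBins)
  k <- dnorm(seq(-half, half), sd = sigmaBins)
  k <- k / sum(k)
  x <- binned@values
  n <- nrow(x)
  sm <- apply(x, 2, function(col) {
    padded <- c(rep(0, half), col, rep(0, half))
    full <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
    full
  })
  # edge renormalization: divide by the kernel mass actually inside
  ones <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)),
                        k, sides = 2)[(half + 1):(half + n)]
  sm <- matrix(sm, n) / as.numeric(ones)
  out <- binned
  out@values <- sm
  out
}

#' Downsample finger position and estimate velocity
#'
#' Positions (1 kHz) are averaged into 20 ms bins, smoothed with a
#' second-order Savitzky-Golay FIR filter (default 7-point window), and
#' velocity is obtained by central differencing of the smoothed positions.
#' The filter is exact on polynomial trajectories of degree <= 2.
#'
#' @param fingerPosition time x k percent-flexion matrix at 1 kHz.
#' @param windowBins odd Savitzky-Golay window length (default 7).
#' @param order polynomial order (default 2).
#' @param originMs clock offset of the trace.
#' @return list of two [BinnedFeatures-class]: `position` (percent) and
#'   `velocity` (percent/s), both kind `"kinematics"` on the 20 ms grid.
#' @export
savgolVelocity <- function(fingerPosition, windowBins = 7L, order = 2L,
                           originMs = 0L) {
  binW <- 20L
  if (nrow(fingerPosition) < windowBins * binW)
    .stopf("savgolVelocity: trace shorter than the filter window")
  posBin <- .binRows(fingerPosition, binW, FUN = "mean")
  sg <- apply(posBin, 2, function(x)
    signal::sgolayfilt(x, p = order, n = windowBins))
  sg <- matrix(sg, nrow(posBin))
  n <- nrow(sg)
  vel <- matrix(0, n, ncol(sg))
  dt <- binW / 1000
  vel[2:(n - 1), ] <- (sg[3:n, , drop = FALSE] -
                       sg[1:(n - 2), , drop = FALSE]) / (2 * dt)
  vel[1, ] <- (sg[2, ] - sg[1, ]) / dt
  vel[n, ] <- (sg[n, ] - sg[n - 1, ]) / dt
  starts <- originMs + (seq_len(n) - 1) * binW
  mk <- function(values, kind) new("BinnedFeatures", values = values,
    binWidthMs = binW, binStartTimesMs = starts,
    channelMask = rep(TRUE, ncol(values)), featureKind = "kinematics")
  list(position = mk(sg), velocity = mk(vel))
}

#' Locate the peak movement of a trial
#'
#' Speed is the Euclidean norm of the active finger groups' velocities on
#' the 20 ms grid; the peak is the largest local speed maximum after
#' target presentation (ties broken by the earlier bin). A monotone trace
#' with no interior local maximum returns the global maximum with
#' `degenerate = TRUE`.
#'
#' @param velocity a [BinnedFeatures-class] of velocities (bins x groups).
#' @param presentationTimeMs trial presentation time on the bin clock.
#' @param endTimeMs trial end time; the search stops at this bin (defaults
#'   to the end of the trace).
#' @param activeDof logical selector of the finger groups with targets.
#' @return list: `peakTimeMs`, `peakBinIndex` (into the velocity grid),
#'   `peakSpeed`, `degenerate`.
#' @export
findPeakMovement <- function(velocity, presentationTimeMs = NULL,
                             endTimeMs = NULL, activeDof = NULL) {
  v <- velocity@values
  if (is.null(activeDof)) activeDof <- rep(TRUE, ncol(v))
  speed <- sqrt(rowSums(v[, activeDof, drop = FALSE]^2))
  starts <- velocity@binStartTimesMs
  from <- if (is.null(presentationTimeMs)) 1L
          else which(starts + velocity@binWidthMs > presentationTimeMs)[1]
  if (is.na(from)) .stopf("findPeakMovement: presentation after trace end")
  to <- if (is.null(endTimeMs)) length(speed)
        else max(from, which(starts < endTimeMs)[sum(starts < endTimeMs)])
  s <- speed[from:to]
  n <- length(s)
  isPeak <- if (n >= 3)
    c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n], FALSE)
  else rep(FALSE, n)
  degenerate <- !any(isPeak)
  cand <- if (degenerate) seq_len(n) else which(isPeak)
  best <- cand[which.max(s[cand])]          # which.max takes the earliest tie
  bin <- from + best - 1L
  list(peakTimeMs = starts[bin], peakBinIndex = bin,
       peakSpeed = speed[bin], degenerate = degenerate)
}

#' Peri-movement average of binned features
#'
#' Mean per channel over the window of `nBefore` bins before the peak bin,
#' the peak bin itself, and `nAfter` bins after it (21 bins at 20 ms =
#' the 420 ms peri-movement window; 20 before / 37 after = the 58-bin
#' manifold window).
#'
#' @param binned a [BinnedFeatures-class].
#' @param peakBin index of the bin containing peak movement.
#' @param nBefore,nAfter window extent in bins.
#' @return named numeric vector, one mean per channel.
#' @export
periMovementAverage <- function(binned, peakBin, nBefore = 10L, nAfter = 10L) {
  lo <- peakBin - nBefore
  hi <- peakBin + nAfter
  if (lo < 1 || hi > nrow(binned@values))
    .stopf("periMovementAverage: window [%d, %d] exceeds the %d-bin slice",
           lo, hi, nrow(binned@values))
  colMeans(binned@values[lo:hi, , drop = FALSE])
}

#' Compare two groups of scalar observations
#'
#' Dispatches the named classical test and returns its statistic, two-sided
#' p-value, and (for t-tests) the confidence interval of the group
#' difference. Two-sample t-tests use pooled variance.
#'
#' @param a,b numeric vectors (for `ks_one_sample`, `b` is ignored and `a`
#'   is tested against a standard normal unless `null_sd` is given).
#' @param kind one of `"two_sample_t"`, `"paired_t"`, `"ks_one_sample"`,
#'   `"ks_two_sample"`.
#' @param ciLevel confidence level for t-test intervals (default 0.99).
#' @param null_sd null standard deviation for the one-sample KS test.
#' @return list: `statistic`, `p`, `ci` (NULL for KS tests), `kind`.
#' @export
compareGroups <- function(a, b = NULL,
                          kind = c("two_sample_t", "paired_t",
                                   "ks_one_sample", "ks_two_sample"),
                          ciLevel = 0.99, null_sd = 1) {
  kind <- match.arg(kind)
  if (kind %in% c("two_sample_t", "paired_t", "ks_two_sample") && is.null(b))
    .stopf("compareGroups: '%s' needs two groups", kind)
  if (kind %in% c("two_sample_t", "paired_t") &&
      stats::var(a) == 0 && (is.null(b) || stats::var(b) == 0))
    .stopf("compareGroups: degenerate test, zero variance in both groups")
  res <- switch(kind,
    two_sample_t = stats::t.test(a, b, var.equal = TRUE,
                                 conf.level = ciLevel),
    paired_t = stats::t.test(a, b, paired = TRUE, conf.level = ciLevel),
    ks_one_sample = suppressWarnings(
      stats::ks.test(a, "pnorm", mean = 0, sd = null_sd)),
    ks_two_sample = suppressWarnings(stats::ks.test(a, b)))
  list(statistic = unname(res$statistic), p = res$p.value,
       ci = if (grepl("_t$", kind)) unname(res$conf.int) else NULL,
       kind = kind)
}
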