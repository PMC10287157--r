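#' @import methods
NULL

.CONTEXTS <- c("normal", "spring", "wrist", "band", "both")
.MODES <- c("manipulandum", "online_kf", "online_rfkf")
.FEATURE_KINDS <- c("sbp", "tcfr", "emg_envelope", "kinematics")

#' Continuous per-session recording streams
#'
#' Holds the millisecond-resolution streams of a session: per-channel
#' spiking band power (SBP) with the raw 2 kHz sample counts that entered
#' each 1 ms value, per-channel threshold-crossing event times, the 1 kHz
#' finger-group position traces, and (optionally) multi-channel EMG.
#' All streams share one clock; `originMs` records the offset of the first
#' sample on the session clock (0 for a full session, nonzero for trial
#' slices cut by [sliceTrial()]).
#'
#' @slot sbp1ms numeric matrix, time (ms) x channels; per-ms rectified sums.
#' @slot rawSampleCount1ms integer matrix, same shape; counts in \{0, 1, 2\}.
#' @slot crossingTimes list of numeric vectors, one per channel, sorted
#'   event times in ms on the session clock.
#' @slot fingerPosition numeric matrix, time (ms) x 2, percent flexion in
#'   \[0, 100\] (columns: index, MRS group).
#' @slot emg numeric matrix (time x channels) or a 0 x 0 matrix when absent.
#' @slot emgRateHz sampling rate of `emg` (10000 for raw EMG, 1000 when the
#'   generator stores envelope-resolution muscle activation).
#' @slot originMs integer scalar, session-clock time of the first sample.
#' @export
setClass("ContinuousStreams",
  representation(
    sbp1ms = "matrix",
    rawSampleCount1ms = "matrix",
    crossingTimes = "list",
    fingerPosition = "matrix",
    emg = "matrix",
    emgRateHz = "numeric",
    originMs = "integer"
  ),
  prototype(
    emg = matrix(numeric(0), 0, 0),
    emgRateHz = 10000,
    originMs = 0L
  )
)

setValidity("ContinuousStreams", function(object) {
  msg <- character(0)
  if (nrow(object@sbp1ms) != nrow(object@rawSampleCount1ms) ||
      ncol(object@sbp1ms) != ncol(object@rawSampleCount1ms))
    msg <- c(msg, "sbp1ms and rawSampleCount1ms must have identical shape")
  if (length(object@crossingTimes) != ncol(object@sbp1ms))
    msg <- c(msg, "crossingTimes must have one element per channel")
  cnt <- object@rawSampleCount1ms
  if (length(cnt) && (min(cnt) < 0 || max(cnt) > 2))
    msg <- c(msg, "rawSampleCount1ms entries must lie in {0,1,2}")
  fp <- object@fingerPosition
  if (length(fp) && (min(fp) < -1e-9 || max(fp) > 100 + 1e-9))
    msg <- c(msg, "fingerPosition must lie in [0,100] percent flexion")
  if (length(fp) && ncol(fp) != 2)
    msg <- c(msg, "fingerPosition must have 2 columns (index, MRS)")
  if (length(object@originMs) != 1)
    msg <- c(msg, "originMs must be a scalar")
  if (length(msg)) msg else TRUE
})

#' A recorded (or simulated) behavioral session
#'
#' Bundles the trial/event table, the continuous streams, and per-trial
#' context-block labels. Trials are rows of a data.frame with columns
#' `trial_index`, `context`, `mode`, `dof`, `target_center_index`,
#' `target_center_mrs`, `target_width`, `presentation_time_ms`,
#' `end_time_ms`, `hold_time_ms`, `success`, `decoder_id`.
#'
#' @slot monkeyId character identifier of the subject.
#' @slot nChannels integer number of neural channels (default 96).
#' @slot trials data.frame of trial records ordered by presentation time.
#' @slot streams a [ContinuousStreams-class] object.
#' @slot contextBlockLabels integer vector, one block id per trial.
#' @slot groundTruth list of generator-side ground truth (empty for
#'   recorded sessions); used by parameter-recovery analyses.
#' @export
setClass("SessionRecord",
  representation(
    monkeyId = "character",
    nChannels = "integer",
    trials = "data.frame",
    streams = "ContinuousStreams",
    contextBlockLabels = "integer",
    groundTruth = "list"
  ),
  prototype(monkeyId = "synthetic", groundTruth = list())
)

.TRIAL_COLS <- c("trial_index", "context", "mode", "dof",
                 "target_center_index", "target_center_mrs", "target_width",
                 "presentation_time_ms", "end_time_ms", "hold_time_ms",
                 "success", "decoder_id")

setValidity("SessionRecord", function(object) {
  msg <- character(0)
  tr <- object@trials
  missing_cols <- setdiff(.TRIAL_COLS, names(tr))
  if (length(missing_cols))
    msg <- c(msg, paste("trial table missing columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols) && nrow(tr)) {
    if (is.unsorted(tr$presentation_time_ms))
      msg <- c(msg, "trials must be ordered by presentation_time_ms")
    if (any(tr$end_time_ms <= tr$presentation_time_ms))
      msg <- c(msg, "end_time_ms must exceed presentation_time_ms")
    ctr <- c(tr$target_center_index, tr$target_center_mrs)
    ctr <- ctr[!is.na(ctr)]
    if (length(ctr) && (min(ctr) < 0 || max(ctr) > 100))
      msg <- c(msg, "target centers must lie in [0,100]")
    if (any(tr$target_width <= 0))
      msg <- c(msg, "target_width must be positive")
    if (!all(tr$context %in% .CONTEXTS))
      msg <- c(msg, "unknown context label in trial table")
    if (length(object@contextBlockLabels) != nrow(tr))
      msg <- c(msg, "contextBlockLabels must have one entry per trial")
  }
  if (ncol(object@streams@sbp1ms) &&
      ncol(object@streams@sbp1ms) != object@nChannels)
    msg <- c(msg, "stream channel count disagrees with nChannels")
  if (length(msg)) msg else TRUE
})

#' Binned neural, muscle, or kinematic features
#'
#' A bins x channels matrix at a stated bin width, with half-open
#' contiguous bins `[start, start + width)` and a per-channel mask.
#'
#' @slot values numeric matrix, bins x channels.
#' @slot binWidthMs integer bin width (20, 32, or 50 ms in this package).
#' @slot binStartTimesMs numeric vector of bin start times (session clock).
#' @slot channelMask logical vector, one flag per channel; masked-out
#'   channels must not be used downstream.
#' @slot featureKind one of "sbp", "tcfr", "emg_envelope", "kinematics".
#' @export
setClass("BinnedFeatures",
  representation(
    values = "matrix",
    binWidthMs = "integer",
    binStartTimesMs = "numeric",
    channelMask = "logical",
    featureKind = "character"
  )
)

setValidity("BinnedFeatures", function(object) {
  msg <- character(0)
  if (length(object@binStartTimesMs) != nrow(object@values))
    msg <- c(msg, "one bin start time per row required")
  if (length(object@channelMask) != ncol(object@values))
    msg <- c(msg, "one mask flag per channel required")
  if (!object@featureKind %in% .FEATURE_KINDS)
    msg <- c(msg, "unknown featureKind")
  if (length(object@binStartTimesMs) > 1) {
    d <- diff(object@binStartTimesMs)
    if (any(abs(d - object@binWidthMs) > 1e-9))
      msg <- c(msg, "bins must be contiguous and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic session generator
#'
#' Describes the planted structure of a simulated session: the latent
#' loading of each channel, per-context muscle gains, the coupling of the
#' context latent to required active-muscle activation, noise levels, and
#' task timing. Construct with [generatorConfig()].
#'
#' @slot seed integer master seed; child seeds per stream derive from it.
#' @slot nChannels,nLatents integers (defaults 96 and 16).
#' @slot latentLoading channels x latents loading matrix.
#' @slot latentGroups integer vector labelling latent columns: 1 =
#'   condition-independent, 2 = target, 3 = context, 4 = interaction.
#' @slot contextGainFlexor,contextGainExtensor named numeric vectors of
#'   per-context multiplicative gains on required muscle activation
#'   (normal = 1).
#' @slot cocontractionGain named numeric vector: extensor activation added
#'   during resisted flexion (co-contraction; nonzero for spring contexts).
#' @slot contextShiftScale scalar coupling the context latent to the
#'   difference in required active-muscle activation from normal.
#' @slot noiseSdSbp,emgNoiseSd positive noise scales.
#' @slot emgBaseline baseline envelope level (a.u.).
#' @slot trialsPerBlock integer length-2 range of trials per context block.
#' @slot reactionTimeMs,reactionTimeJitterMs,movementDurationMs,holdTimeMs,
#'   interTrialMs,leadInMs timing parameters in ms.
#' @slot fractionFailed planted failure probability in \[0, 1).
#' @slot sbpScale,rateScaleHz observation-model scales (SBP amplitude and
#'   threshold-crossing rate multiplier on softplus(drive)).
#' @slot contextLoadingFraction fraction of channels carrying nonzero
#'   context-latent loading (ground truth for power analyses).
#' @slot emgRaw logical; synthesize band-limited 10 kHz raw EMG (TRUE) or
#'   store the 1 kHz envelope (FALSE, default — the envelope is what every
#'   analysis consumes).
#' @export
setClass("GeneratorConfig",
  representation(
    seed = "integer",
    nChannels = "integer",
    nLatents = "integer",
    latentLoading = "matrix",
    latentGroups = "integer",
    contextGainFlexor = "numeric",
    contextGainExtensor = "numeric",
    cocontractionGain = "numeric",
    contextShiftScale = "numeric",
    noiseSdSbp = "numeric",
    emgNoiseSd = "numeric",
    emgBaseline = "numeric",
    trialsPerBlock = "integer",
    reactionTimeMs = "numeric",
    reactionTimeJitterMs = "numeric",
    movementDurationMs = "numeric",
    holdTimeMs = "numeric",
    interTrialMs = "numeric",
    leadInMs = "numeric",
    fractionFailed = "numeric",
    sbpScale = "numeric",
    rateScaleHz = "numeric",
    contextLoadingFraction = "numeric",
    emgRaw = "logical"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  if (any(object@contextGainFlexor <= 0) || any(object@contextGainExtensor <= 0))
    msg <- c(msg, "context gains must be positive")
  if (abs(object@contextGainFlexor[["normal"]] - 1) > 1e-12 ||
      abs(object@contextGainExtensor[["normal"]] - 1) > 1e-12)
    msg <- c(msg, "normal-context gains must equal 1")
  if (ncol(object@latentLoading) != object@nLatents ||
      nrow(object@latentLoading) != object@nChannels)
    msg <- c(msg, "latentLoading must be nChannels x nLatents")
  if (qr(object@latentLoading)$rank < object@nLatents)
    msg <- c(msg, "latentLoading must have full column rank")
  if (length(object@latentGroups) != object@nLatents ||
      !all(object@latentGroups %in% 1:4))
    msg <- c(msg, "latentGroups must label every latent with 1..4")
  if (object@fractionFailed < 0 || object@fractionFailed >= 1)
    msg <- c(msg, "fractionFailed must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Lagged ridge regression decoder
#'
#' Linear map from current-plus-history binned neural features to
#' kinematics or muscle-activation envelopes, fitted by ridge regression
#' with an unpenalized intercept.
#'
#' @slot weights (nMasked * (history+1) + 1) x outputs matrix; last row is
#'   the intercept.
#' @slot ridgeLambda nonnegative penalty.
#' @slot nHistoryBins integer bins of history (default 12).
#' @slot binWidthMs integer (default 32).
#' @slot channelMask logical mask applied before lagging (mean TCFR > 1 Hz
#'   rule).
#' @slot outputKind "kinematics" or "emg_envelope".
#' @slot outputNames character names of output columns.
#' @slot featureCenter,featureScale training-fold standardization of the
#'   lagged design columns.
#' @export
setClass("RidgeDecoder",
  representation(
    weights = "matrix",
    ridgeLambda = "numeric",
    nHistoryBins = "integer",
    binWidthMs = "integer",
    channelMask = "logical",
    outputKind = "character",
    outputNames = "character",
    featureCenter = "numeric",
    featureScale = "numeric"
  )
)

#' Position/velocity Kalman filter decoder
#'
#' Standard linear-Gaussian Kalman filter over the state
#' `[pos_index, pos_mrs, vel_index, vel_mrs, 1]` with a 32 ms update.
#' Position rows of `A` implement physical integration and the constant-1
#' state component is preserved exactly; virtual finger position is updated
#' online by integrating the posterior velocity.
#'
#' @slot A 5 x 5 state-transition matrix.
#' @slot W 5 x 5 process-noise covariance (nonzero only on velocity block).
#' @slot C channels x 5 observation matrix.
#' @slot Q channels x channels observation-noise covariance.
#' @slot binWidthMs integer update interval (default 32).
#' @export
setClass("KalmanDecoder",
  representation(
    A = "matrix", W = "matrix", C = "matrix", Q = "matrix",
    binWidthMs = "integer"
  ),
  prototype(A = diag(5), W = matrix(0, 5, 5), C = matrix(0, 1, 5),
            Q = matrix(0, 1, 1), binWidthMs = 32L)
)

setValidity("KalmanDecoder", function(object) {
  msg <- character(0)
  if (!isTRUE(all.equal(object@W, t(object@W), tolerance = 1e-8)) ||
      !isTRUE(all.equal(object@Q, t(object@Q), tolerance = 1e-8)))
    msg <- c(msg, "W and Q must be symmetric")
  if (max(abs(object@A[5, ] - c(0, 0, 0, 0, 1))) > 1e-10)
    msg <- c(msg, "constant-1 state row of A must be [0,0,0,0,1]")
  if (length(msg)) msg else TRUE
})

#' Behavioral intention model for closed-loop simulation
#'
#' A stand-in for the subject during closed-loop runs: emits a desired
#' velocity toward the current target with a gain, additive noise, an
#' optional per-direction re-aim offset (modelling "pushing harder"), and a
#' reaction time during which no command is issued.
#'
#' @slot gain positive scalar on the distance-proportional command.
#' @slot noiseSd command noise (%/s).
#' @slot reaimOffset length-2 velocity offset added along the target
#'   direction (%/s); 0 disables re-aiming.
#' @slot reactionTimeMs delay before the first command of each trial.
#' @slot feedbackDelayMs visuomotor feedback delay: commands are computed
#'   from the cursor position this long ago.
#' @slot maxSpeed command saturation (%/s).
#' @export
setClass("IntentionModel",
  representation(
    gain = "numeric", noiseSd = "numeric", reaimOffset = "numeric",
    reactionTimeMs = "numeric", feedbackDelayMs = "numeric",
    maxSpeed = "numeric"
  ),
  prototype(gain = 4, noiseSd = 4, reaimOffset = c(0, 0),
            reactionTimeMs = 160, feedbackDelayMs = 160, maxSpeed = 200)
)

setValidity("IntentionModel", function(object) {
  if (object@gain <= 0) "gain must be positive" else TRUE
})

#' Per-context PCA manifold
#'
#' @slot basis channels x K orthonormal matrix of top principal components.
#' @slot explainedVariance per-component variance fractions.
#' @slot context context label the manifold was computed from.
#' @export
setClass("ContextManifold",
  representation(
    basis = "matrix",
    explainedVariance = "numeric",
    context = "character"
  )
)

setValidity("ContextManifold", function(object) {
  g <- crossprod(object@basis)
  if (max(abs(g - diag(ncol(object@basis)))) > 1e-8)
    "basis must be orthonormal" else TRUE
})

#' Demixed PCA decomposition of a condition tensor
#'
#' Components are grouped by the behavioral parameter whose marginalization
#' they reconstruct: condition-independent (time), context, target, or
#' context-target interaction.
#'
#' @slot encoder channels x nComponents matrix (columns grouped by
#'   marginalization).
#' @slot decoder nComponents x channels matrix.
#' @slot componentMarg character vector naming each component's
#'   marginalization.
#' @slot varFractionComponent per-component fraction of total variance.
#' @slot varFractionMarg named per-marginalization variance fractions of
#'   the exact decomposition (sums to 1).
#' @slot margMeans list of the marginalized parts (exact additive
#'   decomposition of the centered condition averages).
#' @slot dims named integer vector (N, C, D, T) of the condition tensor.
#' @export
setClass("DPCAResult",
  representation(
    encoder = "matrix",
    decoder = "matrix",
    componentMarg = "character",
    varFractionComponent = "numeric",
    varFractionMarg = "numeric",
    margMeans = "list",
    dims = "integer"
  )
)

#' Lagged velocity readout for online neural activity patterns
#'
#' Linear regression from the current plus five most recent 50 ms bins of
#' masked channel activity to the two finger-group velocities, trained on
#' normal-context offline trials only.
#'
#' @slot weights (nMasked * 6 + 1) x 2 matrix; last row is the intercept.
#' @slot binWidthMs integer (50).
#' @slot nHistoryBins integer (5).
#' @slot channelMask logical channel mask.
#' @export
setClass("PatternReadout",
  representation(
    weights = "matrix",
    binWidthMs = "integer",
    nHistoryBins = "integer",
    channelMask = "logical"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "SessionRecord", function(object) {
  tr <- object@trials
  cat("SessionRecord:", object@monkeyId, "\n")
  cat("  channels:", object@nChannels,
      " trials:", nrow(tr),
      " duration:", if (nrow(object@streams@sbp1ms))
        sprintf("%.1f s", nrow(object@streams@sbp1ms) / 1000) else "0 s", "\n")
  if (nrow(tr)) {
    cat("  contexts:", paste(sprintf("%s(%d)", names(table(tr$context)),
                                     table(tr$context)), collapse = " "), "\n")
    cat("  success rate:", sprintf("%.1f%%", 100 * mean(tr$success)), "\n")
  }
  cat("  EMG:", if (length(object@streams@emg)) sprintf(
    "%d ch @ %g Hz", ncol(object@streams@emg), object@streams@emgRateHz)
    else "absent", "\n")
})

setMethod("show", "BinnedFeatures", function(object) {
  cat(sprintf("BinnedFeatures[%s]: %d bins x %d channels @ %d ms (%d masked in)\n",
              object@featureKind, nrow(object@values), ncol(object@values),
              object@binWidthMs, sum(object@channelMask)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig: seed", object@seed, "\n")
  cat("  channels:", object@nChannels, " latents:", object@nLatents,
      "(groups:", paste(table(factor(object@latentGroups, 1:4,
        c("cond-indep", "target", "context", "interaction"))), collapse = "/"),
      ")\n")
  cat("  flexor gains:", paste(sprintf("%s=%.2f", names(object@contextGainFlexor),
                                       object@contextGainFlexor), collapse = " "), "\n")
  cat("  extensor gains:", paste(sprintf("%s=%.2f", names(object@contextGainExtensor),
                                         object@contextGainExtensor), collapse = " "), "\n")
})

setMethod("show", "KalmanDecoder", function(object) {
  cat(sprintf("KalmanDecoder: %d-channel observation, %d ms update\n",
              nrow(object@C), object@binWidthMs))
})

setMethod("show", "RidgeDecoder", function(object) {
  cat(sprintf("RidgeDecoder[%s]: %d features -> %d outputs, lambda=%.3g, %d history bins\n",
              object@outputKind, nrow(object@weights) - 1L,
              ncol(object@weights), object@ridgeLambda, object@nHistoryBins))
})

setMethod("show", "DPCAResult", function(object) {
  cat("DPCAResult:", length(object@componentMarg), "components\n")
  vf <- object@varFractionMarg
  cat("  marginalization variance:",
      paste(sprintf("%s=%.1f%%", names(vf), 100 * vf), collapse = " "), "\n")
})

setMethod("show", "ContextManifold", function(object) {
  cat(sprintf("ContextManifold[%s]: %d x %d basis, %.1f%% variance\n",
              object@context, nrow(object@basis), ncol(object@basis),
              100 * sum(object@explainedVariance)))
})
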