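## Synthetic session generator.
##
## Sessions are built from a planted low-dimensional latent structure:
## condition-independent (trial phase), target (signed kinematics), context
## (difference in required active-muscle activation from the normal
## context), and target-x-context interaction latents drive the channels
## through a fixed loading matrix. Muscle envelopes are constructed first,
## so the context latent's coupling to required muscle activation is a
## property of the construction that downstream analyses can recover, not a
## hard-coded output.

.CTX_FLEX_GAIN <- c(normal = 1, spring = 1.92, wrist = 1.53,
                    band = 2.50, both = 1.92 * 1.53)
.CTX_EXT_GAIN <- c(normal = 1, spring = 0.92, wrist = 0.68,
                   band = 0.85, both = 0.92 * 0.68)
.CTX_COCONTRACTION <- c(normal = 0, spring = 0.35, wrist = 0,
                        band = 0.45, both = 0.35)

#' Create a synthetic-session generator configuration
#'
#' Defaults reproduce the study conditions the analyses assume: 96 channels
#' driven by 16 latents, per-context multiplicative gains on required
#' muscle activation (spring: flexors x1.92, extensors x0.92; wrist:
#' flexors x1.53, extensors x0.68; band and combined contexts composed from
#' these), co-contraction of extensors during resisted flexion, context
#' blocks of 175-350 trials, and a 500 ms minimum-jerk movement.
#'
#' @param seed master seed; every stream derives a child seed from it.
#' @param nChannels,nLatents dimensions of the planted model.
#' @param latentLoading optional channels x latents loading; generated
#'   deterministically from `seed` when NULL.
#' @param contextGainFlexor,contextGainExtensor,cocontractionGain named
#'   per-context scalars (see Details for defaults).
#' @param contextShiftScale coupling of the context latents to the change
#'   in required active-muscle activation.
#' @param noiseSdSbp,emgNoiseSd,emgBaseline noise and baseline levels (a.u.).
#' @param trialsPerBlock length-2 integer range of trials per context block.
#' @param reactionTimeMs,reactionTimeJitterMs,movementDurationMs,holdTimeMs
#'   task timing (ms).
#' @param leadInMs idle recording before the first trial.
#' @param fractionFailed planted failure probability.
#' @param sbpScale,rateScaleHz observation scales (SBP amplitude;
#'   threshold-crossing rate is `rateScaleHz * softplus(drive)` Hz).
#' @param contextLoadingFraction fraction of channels with nonzero
#'   context-latent loading (the ground-truth "context modulated" set).
#' @param emgRaw synthesize 10 kHz band-limited raw EMG instead of storing
#'   the 1 kHz envelope.
#' @return a validated [GeneratorConfig-class] object.
#' @export
generatorConfig <- function(seed = 1L, nChannels = 96L, nLatents = 16L,
                            latentLoading = NULL,
                            contextGainFlexor = .CTX_FLEX_GAIN,
                            contextGainExtensor = .CTX_EXT_GAIN,
                            cocontractionGain = .CTX_COCONTRACTION,
                            contextShiftScale = 1.5,
                            noiseSdSbp = 0.5,
                            emgNoiseSd = 0.02,
                            emgBaseline = 0.2,
                            trialsPerBlock = c(175L, 350L),
                            reactionTimeMs = 180,
                            reactionTimeJitterMs = 80,
                            movementDurationMs = 500,
                            holdTimeMs = 750,
                            interTrialMs = 0,
                            leadInMs = 800,
                            fractionFailed = 0.03,
                            sbpScale = 1,
                            rateScaleHz = 20,
                            contextLoadingFraction = 0.6,
                            emgRaw = FALSE) {
  nChannels <- as.integer(nChannels); nLatents <- as.integer(nLatents)
  groups <- .latentGroupLabels(nLatents)
  if (is.null(latentLoading))
    latentLoading <- .buildLoading(seed, nChannels, nLatents, groups,
                                   contextLoadingFraction)
  new("GeneratorConfig", seed = as.integer(seed), nChannels = nChannels,
      nLatents = nLatents, latentLoading = latentLoading,
      latentGroups = groups,
      contextGainFlexor = contextGainFlexor,
      contextGainExtensor = contextGainExtensor,
      cocontractionGain = cocontractionGain,
      contextShiftScale = contextShiftScale,
      noiseSdSbp = noiseSdSbp, emgNoiseSd = emgNoiseSd,
      emgBaseline = emgBaseline,
      trialsPerBlock = as.integer(trialsPerBlock),
      reactionTimeMs = reactionTimeMs,
      reactionTimeJitterMs = reactionTimeJitterMs,
      movementDurationMs = movementDurationMs,
      holdTimeMs = holdTimeMs, interTrialMs = interTrialMs,
      leadInMs = leadInMs, fractionFailed = fractionFailed,
      sbpScale = sbpScale, rateScaleHz = rateScaleHz,
      contextLoadingFraction = contextLoadingFraction,
      emgRaw = emgRaw)
}

# Latent group labels: 1 cond-independent, 2 target, 3 context,
# 4 interaction, split roughly 1/4, 3/8, 3/16, 3/16 of nLatents.
.latentGroupLabels <- function(nLatents) {
  nCI <- max(1L, round(nLatents / 4))
  nTg <- max(2L, round(nLatents * 3 / 8))
  nCx <- max(1L, round(nLatents * 3 / 16))
  nIx <- nLatents - nCI - nTg - nCx
  if (nIx < 1L) .stopf("nLatents too small to host all four latent groups")
  as.integer(rep(1:4, c(nCI, nTg, nCx, nIx)))
}

.buildLoading <- function(seed, nChannels, nLatents, groups, ctxFraction) {
  .withSeed(seed, "loading", {
    L <- matrix(rnorm(nChannels * nLatents, sd = 1 / sqrt(nLatents)),
                nChannels, nLatents)
    ctx_cols <- which(groups >= 3)        # context + interaction columns
    # keep at least nLatents context-loaded channels so the loading stays
    # full column rank after the orthogonalization below
    n_off <- min(round((1 - ctxFraction) * nChannels),
                 nChannels - nLatents)
    if (n_off > 0) {
      off <- sample(nChannels, n_off)
      L[off, ctx_cols] <- 0
    }
    # The context shift occupies population directions orthogonal to the
    # movement-coding subspace (within the rows of the context-loaded
    # channels, so context-blind channels keep exact zeros). The context
    # columns share one "effort direction" u whose per-channel magnitude
    # is floored, so every context-loaded channel carries a recoverable
    # planted effect; small complement-space jitter keeps the block full
    # rank. Interaction columns are plain orthogonalized noise.
    on <- which(rowSums(abs(L[, ctx_cols, drop = FALSE])) > 0)
    movOn <- qr.Q(qr(L[on, -ctx_cols, drop = FALSE]))
    P <- diag(length(on)) - tcrossprod(movOn)
    u <- drop(P %*% rnorm(length(on)))
    flr <- 0.7
    for (it in 1:50) {
      weak <- which(abs(u) < flr)
      if (!length(weak)) break
      for (i in weak) {
        s_i <- if (u[i] >= 0) 1 else -1
        u <- u + P[, i] * s_i * (flr - s_i * u[i]) / P[i, i]
      }
    }
    nCx <- sum(groups == 3L)
    jit <- function() drop(P %*% rnorm(length(on))) * 0.25
    cxBlock <- sapply(seq_len(nCx), function(j)
      c(1, 0.6, 0.4)[((j - 1) %% 3) + 1] * u + if (j > 1) jit() else 0)
    ixBlock <- L[on, which(groups == 4L), drop = FALSE]
    ixBlock <- ixBlock - movOn %*% crossprod(movOn, ixBlock)
    block <- cbind(cxBlock, ixBlock)
    # match the per-entry scale of the rest of the loading
    block <- block / sqrt(mean(block^2)) * (1.5 / sqrt(nLatents))
    L[on, ctx_cols] <- block
    L
  })
}

# Per-channel positive baseline drive (keeps SBP in the near-linear regime
# of the rectifier, like a baseline firing level).
.channelBaseline <- function(config) {
  .withSeed(config@seed, "baseline",
            rnorm(config@nChannels, mean = 1, sd = 0.15))
}

# Per-muscle envelope weights: 8 channels, 1-4 flexors, 5-8 extensors.
.muscleWeights <- function(config) {
  .withSeed(config@seed, "muscles", runif(8, 0.8, 1.2))
}

#' Which EMG channels are finger flexors / extensors
#'
#' The simulated EMG montage has eight channels: 1-4 are flexor muscles,
#' 5-8 extensor muscles.
#' @return list with integer vectors `flexor` and `extensor`.
#' @export
muscleGroups <- function() list(flexor = 1:4, extensor = 5:8)

## ---- kinematics ---------------------------------------------------------

# Minimum-jerk unit profile and its derivative over n integer ms.
.minJerk <- function(n) {
  tau <- (seq_len(n) - 0.5) / n
  list(s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
       ds = (30 * tau^2 - 60 * tau^3 + 30 * tau^4))   # d s / d tau
}

#' Generate the finger kinematics of one trial
#'
#' After a reaction delay, position follows a minimum-jerk trajectory from
#' the start position to the target center over `movementDurationMs`, then
#' holds inside the target. Velocity is the analytic derivative of the
#' trajectory (peak speed `15 A / (8 T)` for amplitude `A` and duration
#' `T`).
#'
#' @param target length-2 target center (percent flexion; index, MRS).
#' @param startPos length-2 starting position.
#' @param config a [GeneratorConfig-class].
#' @param reactionMs reaction delay before movement onset (ms).
#' @param holdMs hold duration after the movement (ms).
#' @return list with `position` and `velocity` (T x 2 matrices, 1 kHz;
#'   velocity in percent/s) and `movementStartMs`.
#' @export
makeKinematics <- function(target, startPos, config,
                           reactionMs = config@reactionTimeMs,
                           holdMs = config@holdTimeMs) {
  reactionMs <- as.integer(round(reactionMs))
  moveMs <- as.integer(round(config@movementDurationMs))
  holdMs <- as.integer(round(holdMs))
  n <- reactionMs + moveMs + holdMs
  pos <- matrix(0, n, 2); vel <- matrix(0, n, 2)
  mj <- .minJerk(moveMs)
  for (d in 1:2) {
    A <- target[d] - startPos[d]
    p <- c(rep(startPos[d], reactionMs),
           startPos[d] + A * mj$s,
           rep(target[d], holdMs))
    v <- c(rep(0, reactionMs),
           A * mj$ds / (moveMs / 1000),   # percent per second
           rep(0, holdMs))
    pos[, d] <- p; vel[, d] <- v
  }
  pos <- pmin(pmax(pos, 0), 100)
  list(position = pos, velocity = vel, movementStartMs = reactionMs)
}

## ---- muscle activity ----------------------------------------------------

# Envelope from flexion velocity with per-sample gains; vflex in %/s.
.muscleEnvelope <- function(vflex, gF, gE, coco, config) {
  w <- .muscleWeights(config)
  gr <- muscleGroups()
  rpos <- .rectify(vflex) / 100
  rneg <- .rectify(-vflex) / 100
  env <- matrix(config@emgBaseline, length(vflex), 8)
  for (m in gr$flexor)
    env[, m] <- env[, m] + gF * w[m] * rpos
  for (m in gr$extensor)
    env[, m] <- env[, m] + gE * w[m] * rneg + coco * rpos
  env
}

#' Generate muscle activation for a kinematic trace
#'
#' Flexor-group envelopes scale rectified flexion velocity by the context's
#' flexor gain; extensor-group envelopes scale rectified extension velocity
#' by the extensor gain plus a co-contraction term active during resisted
#' flexion. Optionally synthesizes raw 10 kHz EMG as envelope-modulated
#' band-limited (100-500 Hz) noise whose binned mean absolute value
#' recovers the envelope.
#'
#' @param kinematics list with a `velocity` T x 2 matrix (1 kHz), as
#'   returned by [makeKinematics()].
#' @param context context label.
#' @param config a [GeneratorConfig-class].
#' @param activeDof logical length-2; which finger groups have targets.
#' @param raw overrides `config@emgRaw`.
#' @return list with `envelope` (T x 8, 1 kHz) and `raw` (10T x 8 at
#'   10 kHz, or NULL).
#' @export
makeMuscleActivity <- function(kinematics, context, config,
                               activeDof = c(TRUE, TRUE),
                               raw = config@emgRaw) {
  if (!context %in% names(config@contextGainFlexor))
    .stopf("makeMuscleActivity: unknown context '%s'", context)
  v <- kinematics$velocity
  vflex <- rowMeans(v[, activeDof, drop = FALSE])
  env <- .muscleEnvelope(vflex,
                         config@contextGainFlexor[[context]],
                         config@contextGainExtensor[[context]],
                         config@cocontractionGain[[context]],
                         config)
  rawEmg <- NULL
  if (raw) rawEmg <- .rawEmgFromEnvelope(env, config)
  list(envelope = env, raw = rawEmg)
}

# Band-limited carrier noise in 100-500 Hz at 10 kHz, unit mean absolute
# value, multiplied by the upsampled envelope plus measurement noise.
.rawEmgFromEnvelope <- function(env, config) {
  n10 <- nrow(env) * 10L
  bf <- signal::butter(2, c(100, 500) / 5000, type = "pass")
  .withSeed(config@seed, "emg-carrier", {
    raw <- matrix(0, n10, ncol(env))
    for (m in seq_len(ncol(env))) {
      carrier <- as.numeric(signal::filter(bf, rnorm(n10)))
      carrier <- carrier / mean(abs(carrier))
      e10 <- rep(env[, m], each = 10L)
      raw[, m] <- e10 * carrier + config@emgNoiseSd * rnorm(n10)
    }
    raw
  })
}

## ---- latents ------------------------------------------------------------

.lagSeries <- function(x, lagMs) {
  n <- length(x)
  if (lagMs <= 0 || lagMs >= n) return(x)
  c(rep(x[1], lagMs), x[seq_len(n - lagMs)])
}

#' Construct the planted latent timecourses
#'
#' Builds the time x latent matrix driving the neural channels:
#' condition-independent latents follow the trial phase and unsigned speed;
#' target latents are the signed kinematic profiles per finger group;
#' context latents equal `contextShiftScale` times the difference between
#' the active-muscle envelope and its normal-context counterpart (hence
#' identically zero in the normal context); interaction latents are small
#' target-by-context products.
#'
#' @param kinematics list with `position` and `velocity` (T x 2, 1 kHz).
#' @param muscleEnv T x 8 envelope for the trial's context.
#' @param config a [GeneratorConfig-class].
#' @param muscleEnvNormal matching envelope for the normal context
#'   (recomputed when NULL).
#' @param phase T-length trial phase in \[0, 1\] (a linear ramp when NULL).
#' @param activeDof logical length-2 active finger groups.
#' @param context context label (used only to recompute the normal
#'   counterpart when `muscleEnvNormal` is NULL).
#' @return list with `z` (T x nLatents) and `groups` (latent group labels).
#' @export
makeLatents <- function(kinematics, muscleEnv, config,
                        muscleEnvNormal = NULL, phase = NULL,
                        activeDof = c(TRUE, TRUE), context = "normal") {
  v <- kinematics$velocity
  p <- kinematics$position
  n <- nrow(v)
  if (is.null(phase)) phase <- (seq_len(n) - 0.5) / n
  if (is.null(muscleEnvNormal)) {
    vflex <- rowMeans(v[, activeDof, drop = FALSE])
    muscleEnvNormal <- .muscleEnvelope(vflex, 1, 1, 0, config)
  }
  gr <- muscleGroups()
  dFlex <- rowMeans(muscleEnv[, gr$flexor, drop = FALSE]) -
    rowMeans(muscleEnvNormal[, gr$flexor, drop = FALSE])
  dExt <- rowMeans(muscleEnv[, gr$extensor, drop = FALSE]) -
    rowMeans(muscleEnvNormal[, gr$extensor, drop = FALSE])

  speed <- sqrt(rowSums(v^2)) / 100
  groups <- config@latentGroups
  z <- matrix(0, n, config@nLatents)

  ci <- which(groups == 1L)
  ciBank <- cbind(sin(pi * phase), speed, cos(pi * phase) * 0.5,
                  .lagSeries(speed, 60L))
  for (i in seq_along(ci)) z[, ci[i]] <- ciBank[, ((i - 1) %% 4) + 1]

  tg <- which(groups == 2L)
  tgBank <- cbind((p[, 1] - 50) / 40, v[, 1] / 150,
                  (p[, 2] - 50) / 40, v[, 2] / 150,
                  .lagSeries(v[, 1] / 150, 60L),
                  .lagSeries(v[, 2] / 150, 60L))
  for (i in seq_along(tg)) z[, tg[i]] <- tgBank[, ((i - 1) %% 6) + 1]

  cx <- which(groups == 3L)
  sc <- config@contextShiftScale
  # context latents are time-shifted copies of one signed effort shift:
  # positive when the active muscle needs more activation than in the
  # normal context (resisted flexion) and when the antagonist needs less
  # (assisted extension); a single population direction thereby tracks
  # required muscle activation across contexts
  eShift <- dFlex - dExt
  cxBank <- cbind(sc * eShift,
                  sc * 0.6 * .lagSeries(eShift, 80L),
                  sc * 0.4 * .lagSeries(eShift, 160L))
  for (i in seq_along(cx)) z[, cx[i]] <- cxBank[, ((i - 1) %% 3) + 1]

  ix <- which(groups == 4L)
  # slow envelope of the effort shift times target position profiles:
  # small context-by-target products whose time course differs from the
  # phasic effort shift itself
  eSlow <- as.numeric(stats::filter(abs(eShift), rep(1 / 400, 400),
                                    sides = 2))
  eSlow[is.na(eSlow)] <- 0
  ixBank <- cbind(0.3 * eSlow * tgBank[, 1],
                  0.3 * eSlow * tgBank[, 3],
                  0.3 * eSlow * tgBank[, 2])
  for (i in seq_along(ix)) z[, ix[i]] <- ixBank[, ((i - 1) %% 3) + 1]

  list(z = z, groups = groups)
}

## ---- neural observation model ------------------------------------------

#' Generate neural streams from latent timecourses
#'
#' Channel drive is `baseline + loading %*% z + noise`; the per-ms SBP
#' stream is the rectified drive (each 1 ms value carrying a raw 2 kHz
#' sample count of 2), and threshold crossings are drawn from an
#' inhomogeneous Poisson process with rate `rateScaleHz * softplus(drive)`.
#'
#' @param latents list from [makeLatents()] (or any T x nLatents `z`).
#' @param config a [GeneratorConfig-class].
#' @param seedStream child-seed label, so regenerating a single stream is
#'   reproducible on its own.
#' @return list with `sbp1ms`, `rawSampleCount1ms`, `crossingTimes`.
#' @export
makeNeural <- function(latents, config, seedStream = "neural") {
  z <- if (is.list(latents)) latents$z else latents
  stopifnot(all(is.finite(z)))
  n <- nrow(z)
  base <- .channelBaseline(config)
  driveClean <- z %*% t(config@latentLoading)
  driveClean <- sweep(driveClean, 2, base, "+")
  .withSeed(config@seed, seedStream, {
    sbp <- matrix(0, n, config@nChannels)
    crossings <- vector("list", config@nChannels)
    for (ch in seq_len(config@nChannels)) {
      d <- driveClean[, ch] + rnorm(n, sd = config@noiseSdSbp)
      sbp[, ch] <- config@sbpScale * .rectify(d)
      pEvent <- config@rateScaleHz * .softplus(d) / 1000
      crossings[[ch]] <- which(runif(n) < pEvent) - 1L  # ms, 0-based ticks
    }
    list(sbp1ms = sbp,
         rawSampleCount1ms = matrix(2L, n, config@nChannels),
         crossingTimes = lapply(crossings, as.numeric))
  })
}

## ---- session assembly ---------------------------------------------------

.TARGET_WIDTH <- 15

# Draw the non-center target for one trial.
.drawOutTarget <- function(task, rng_magnitudes = c(20, 30, 40)) {
  if (task == "1dof") {
    a <- sample(c(-40, 40), 1)
    c(50 + a, 50 + a)
  } else {
    repeat {
      dirs <- sample(c(-1, 0, 1), 2, replace = TRUE)
      if (any(dirs != 0)) break
    }
    mag <- if (all(dirs != 0) && dirs[1] != dirs[2])
      sample(c(20, 30), 1) else sample(rng_magnitudes, 1)
    pmin(pmax(50 + dirs * mag, 0), 100)
  }
}

#' Generate a complete synthetic session
#'
#' Emits a validated [SessionRecord-class]: center-out-and-back target
#' order (every other target at the 50% center; center re-presented after
#' any failed trial), context blocks per the schedule, planted failures at
#' `fractionFailed`, and all continuous streams (SBP, raw counts,
#' threshold crossings, finger position, muscle activation).
#'
#' @param config a [GeneratorConfig-class].
#' @param contextSchedule either a character vector of block contexts
#'   (block lengths drawn from `config@trialsPerBlock`) or a list of
#'   `list(context =, nTrials =)` blocks.
#' @param task `"1dof"` (targets at +/-40% from center, both finger groups
#'   yoked) or `"2dof"` (center-out combinations at 20/30/40% magnitude).
#' @param mode trial mode label stored in the trial table.
#' @return a [SessionRecord-class] with generator ground truth attached
#'   (latent loading, latent groups, context-loaded channel set, planted
#'   gains).
#' @export
generateSession <- function(config, contextSchedule = c("normal", "spring"),
                            task = c("1dof", "2dof"),
                            mode = "manipulandum") {
  task <- match.arg(task)
  if (length(contextSchedule) == 0)
    .stopf("generateSession: empty context schedule")
  if (is.character(contextSchedule))
    contextSchedule <- lapply(contextSchedule, function(cx)
      list(context = cx, nTrials = NA_integer_))
  bad <- vapply(contextSchedule, function(b)
    !is.list(b) || !b$context %in% .CONTEXTS, logical(1))
  if (any(bad)) .stopf("generateSession: invalid context schedule")

  ## --- trial plan -------------------------------------------------------
  plan <- .withSeed(config@seed, "plan", {
    rows <- list()
    idx <- 0L
    presentCenter <- FALSE   # out/center alternation continues across blocks
    for (b in seq_along(contextSchedule)) {
      blk <- contextSchedule[[b]]
      nTr <- blk$nTrials
      if (is.na(nTr)) {
        rng <- seq(config@trialsPerBlock[1], config@trialsPerBlock[2])
        nTr <- if (length(rng) == 1L) rng else sample(rng, 1)
      }
      nTr <- as.integer(nTr)
      for (k in seq_len(nTr)) {
        idx <- idx + 1L
        target <- if (presentCenter) c(50, 50) else .drawOutTarget(task)
        failed <- runif(1) < config@fractionFailed
        reaction <- config@reactionTimeMs +
          runif(1, 0, config@reactionTimeJitterMs)
        rows[[idx]] <- data.frame(
          trial_index = idx, context = blk$context, block = b,
          target_center_index = target[1], target_center_mrs = target[2],
          reaction_ms = round(reaction), success = !failed)
        # center-out-and-back; center re-presented after any failure
        presentCenter <- if (failed) TRUE else !presentCenter
      }
    }
    do.call(rbind, rows)
  })

  nTrials <- nrow(plan)
  moveMs <- as.integer(round(config@movementDurationMs))
  holdMs <- as.integer(round(config@holdTimeMs))
  durations <- plan$reaction_ms + moveMs + holdMs
  presentation <- as.integer(config@leadInMs + c(0, cumsum(durations))[seq_len(nTrials)])
  endTimes <- as.integer(presentation + durations)
  totalMs <- as.integer(config@leadInMs + sum(durations))

  ## --- kinematics + per-sample context gains ----------------------------
  pos <- matrix(50, totalMs, 2)
  vel <- matrix(0, totalMs, 2)
  phase <- numeric(totalMs)
  gF <- rep(1, totalMs); gE <- rep(1, totalMs); coco <- rep(0, totalMs)
  current <- c(50, 50)
  for (i in seq_len(nTrials)) {
    tgt <- c(plan$target_center_index[i], plan$target_center_mrs[i])
    reach <- if (plan$success[i]) tgt else current + 0.5 * (tgt - current)
    kin <- makeKinematics(reach, current, config,
                          reactionMs = plan$reaction_ms[i], holdMs = holdMs)
    rowsI <- seq.int(presentation[i] + 1L, endTimes[i])
    pos[rowsI, ] <- kin$position
    vel[rowsI, ] <- kin$velocity
    phase[rowsI] <- (seq_along(rowsI) - 0.5) / length(rowsI)
    cx <- plan$context[i]
    gF[rowsI] <- config@contextGainFlexor[[cx]]
    gE[rowsI] <- config@contextGainExtensor[[cx]]
    coco[rowsI] <- config@cocontractionGain[[cx]]
    current <- reach
  }

  ## --- muscles, latents, neural -----------------------------------------
  activeDof <- c(TRUE, TRUE)
  vflex <- rowMeans(vel[, activeDof, drop = FALSE])
  env <- .muscleEnvelope(vflex, gF, gE, coco, config)
  envNormal <- .muscleEnvelope(vflex, 1, 1, 0, config)
  lat <- makeLatents(list(position = pos, velocity = vel), env, config,
                     muscleEnvNormal = envNormal, phase = phase)
  neural <- makeNeural(lat, config)

  emg <- if (config@emgRaw) .rawEmgFromEnvelope(env, config) else {
    .withSeed(config@seed, "emg-noise",
              env + config@emgNoiseSd * matrix(rnorm(length(env)), nrow(env)))
  }
  emgRate <- if (config@emgRaw) 10000 else 1000

  trialsDf <- data.frame(
    trial_index = plan$trial_index,
    context = plan$context,
    mode = mode,
    dof = if (task == "1dof") "one" else "two",
    target_center_index = plan$target_center_index,
    target_center_mrs = plan$target_center_mrs,
    target_width = .TARGET_WIDTH,
    presentation_time_ms = presentation,
    end_time_ms = endTimes,
    hold_time_ms = holdMs,
    success = plan$success,
    decoder_id = NA_character_,
    stringsAsFactors = FALSE)

  st <- continuousStreams(neural$sbp1ms, neural$rawSampleCount1ms,
                          neural$crossingTimes, pos, emg,
                          emgRateHz = emgRate, originMs = 0L)
  ctxCols <- which(config@latentGroups >= 3L)
  # ground-truth context modulation is functional: a channel counts as
  # modulated when its realized context-driven drive carries at least 10%
  # of its total drive SD (loadings on the collinear context latents can
  # cancel, leaving a "loaded" channel with no realized modulation)
  driveCx <- lat$z[, ctxCols, drop = FALSE] %*%
    t(config@latentLoading[, ctxCols, drop = FALSE])
  driveAll <- lat$z %*% t(config@latentLoading)
  sdCx <- apply(driveCx, 2, stats::sd)
  sdAll <- apply(driveAll, 2, stats::sd)
  gt <- list(
    config = config,
    latentLoading = config@latentLoading,
    latentGroups = config@latentGroups,
    contextChannels = which(sdCx > 0.1 * sdAll),
    contextDriveSd = sdCx,
    contextGainFlexor = config@contextGainFlexor,
    contextGainExtensor = config@contextGainExtensor,
    muscleEnvelopeClean = env)
  sessionRecord(trialsDf, st, monkeyId = "synthetic",
                nChannels = config@nChannels,
                contextBlockLabels = plan$block,
                groundTruth = gt)
}

#' Serialize a generator configuration to YAML
#'
#' Writes every scalar and vector field; the loading matrix itself is not
#' stored (it regenerates deterministically from the seed) unless it was
#' user-supplied, in which case it is written as a nested list.
#'
#' @param config a [GeneratorConfig-class].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeGeneratorConfig <- function(config, path) {
  auto <- .buildLoading(config@seed, config@nChannels, config@nLatents,
                        config@latentGroups, config@contextLoadingFraction)
  fields <- list(
    seed = config@seed, n_channels = config@nChannels,
    n_latents = config@nLatents,
    context_gain_flexor = as.list(config@contextGainFlexor),
    context_gain_extensor = as.list(config@contextGainExtensor),
    cocontraction_gain = as.list(config@cocontractionGain),
    context_shift_scale = config@contextShiftScale,
    noise_sd_sbp = config@noiseSdSbp, emg_noise_sd = config@emgNoiseSd,
    emg_baseline = config@emgBaseline,
    trials_per_block = as.integer(config@trialsPerBlock),
    reaction_time_ms = config@reactionTimeMs,
    reaction_time_jitter_ms = config@reactionTimeJitterMs,
    movement_duration_ms = config@movementDurationMs,
    hold_time_ms = config@holdTimeMs,
    inter_trial_ms = config@interTrialMs, lead_in_ms = config@leadInMs,
    fraction_failed = config@fractionFailed,
    sbp_scale = config@sbpScale, rate_scale_hz = config@rateScaleHz,
    context_loading_fraction = config@contextLoadingFraction,
    emg_raw = config@emgRaw)
  if (!isTRUE(all.equal(auto, config@latentLoading)))
    fields$latent_loading <- apply(config@latentLoading, 1, as.list)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Read a generator configuration from YAML
#' @param path YAML file written by [writeGeneratorConfig()].
#' @return a validated [GeneratorConfig-class].
#' @export
readGeneratorConfig <- function(path) {
  f <- yaml::read_yaml(path)
  loading <- NULL
  if (!is.null(f$latent_loading))
    loading <- t(vapply(f$latent_loading, as.numeric,
                        numeric(f$n_latents)))
  generatorConfig(
    seed = f$seed, nChannels = f$n_channels, nLatents = f$n_latents,
    latentLoading = loading,
    contextGainFlexor = unlist(f$context_gain_flexor),
    contextGainExtensor = unlist(f$context_gain_extensor),
    cocontractionGain = unlist(f$cocontraction_gain),
    contextShiftScale = f$context_shift_scale,
    noiseSdSbp = f$noise_sd_sbp, emgNoiseSd = f$emg_noise_sd,
    emgBaseline = f$emg_baseline,
    trialsPerBlock = f$trials_per_block,
    reactionTimeMs = f$reaction_time_ms,
    reactionTimeJitterMs = f$reaction_time_jitter_ms,
    movementDurationMs = f$movement_duration_ms,
    holdTimeMs = f$hold_time_ms, interTrialMs = f$inter_trial_ms,
    leadInMs = f$lead_in_ms, fractionFailed = f$fraction_failed,
    sbpScale = f$sbp_scale, rateScaleHz = f$rate_scale_hz,
    contextLoadingFraction = f$context_loading_fraction,
    emgRaw = f$emg_raw)
}
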