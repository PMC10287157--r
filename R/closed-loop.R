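## Closed-loop BMI simulation: a linear neural encoder stands in for the
## recorded population, an intention model stands in for the subject, and
## the fitted Kalman decoder closes the loop at the 32 ms update rate.

#' Linear neural encoder for closed-loop simulation
#'
#' Maps the behavioral state `[pos_index, pos_mrs, vel_index, vel_mrs, 1]`
#' to channel features with additive Gaussian noise. Channels whose
#' index-flexion velocity loading is positive are "flexor-linked": a
#' context gain applied to them scales their movement-driven activity
#' during flexion pushes (resisted flexion requires more activation),
#' emulating a physical context change the decoder was not trained on.
#'
#' @param nChannels number of channels (default 96).
#' @param seed deterministic construction seed.
#' @param noiseSd feature noise (default 0.3).
#' @return list with `C` (channels x 5), `noiseSd`, `flexorChannels`.
#' @export
linearEncoder <- function(nChannels = 96L, seed = 1L, noiseSd = 0.3) {
  C <- .withSeed(seed, "encoder", cbind(
    matrix(stats::rnorm(nChannels * 2, sd = 0.004), nChannels, 2),
    matrix(stats::rnorm(nChannels * 2, sd = 0.015), nChannels, 2),
    stats::rnorm(nChannels, mean = 1, sd = 0.2)))
  list(C = C, noiseSd = noiseSd, flexorChannels = which(C[, 3] > 0))
}

.encodeFeatures <- function(encoder, state, contextGain = 1) {
  f <- drop(encoder$C %*% state)
  if (contextGain != 1) {
    # the context scales the movement-driven activity of flexor-linked
    # channels during flexion pushes (resisted flexion needs more
    # activation); baseline and position-related activity are unchanged
    vContrib <- drop(encoder$C[encoder$flexorChannels, 3:4, drop = FALSE] %*%
                       state[3:4])
    f[encoder$flexorChannels] <- f[encoder$flexorChannels] +
      (contextGain - 1) * pmax(vContrib, 0)
  }
  f + stats::rnorm(length(f), sd = encoder$noiseSd)
}

#' Simulate open-loop (manipulandum) training data
#'
#' Center-out-and-back minimum-jerk trials on the 32 ms grid with features
#' from a [linearEncoder()]; the standard way to obtain matched training
#' data for [fitKalman()].
#'
#' @param encoder a [linearEncoder()].
#' @param nTrials number of trials (default 300).
#' @param seed RNG seed.
#' @param binWidthMs update interval.
#' @param task `"1dof"` or `"2dof"`.
#' @return list: `features`, `kinematics` (bins x 4), `trialId`.
#' @export
simulateTrainingData <- function(encoder, nTrials = 300L, seed = 1L,
                                 binWidthMs = 32L, task = "2dof") {
  .withSeed(seed, "train", {
    dt <- binWidthMs / 1000
    kin <- list(); tid <- list()
    cur <- c(50, 50)
    presentCenter <- FALSE
    for (i in seq_len(nTrials)) {
      tgt <- if (presentCenter) c(50, 50) else .drawOutTarget(task)
      presentCenter <- !presentCenter
      nMove <- round(0.5 / dt); nHold <- round(0.6 / dt)
      mj <- .minJerk(nMove)
      pos <- rbind(outer(mj$s, tgt - cur) + rep(cur, each = nMove),
                   matrix(tgt, nHold, 2, byrow = TRUE))
      vel <- rbind(outer(mj$ds / (nMove * dt), tgt - cur),
                   matrix(0, nHold, 2))
      kin[[i]] <- cbind(pos, vel)
      tid[[i]] <- rep(i, nMove + nHold)
      cur <- tgt
    }
    kinematics <- do.call(rbind, kin)
    S <- cbind(kinematics, 1)
    features <- S %*% t(encoder$C) +
      matrix(stats::rnorm(nrow(S) * nrow(encoder$C), sd = encoder$noiseSd),
             nrow(S))
    list(features = features, kinematics = kinematics,
         trialId = unlist(tid))
  })
}

#' Construct an intention model
#' @param gain distance-proportional command gain (1/s).
#' @param noiseSd command noise (%/s).
#' @param reaimOffset re-aim velocity offset along the target direction
#'   (%/s); models "pushing harder".
#' @param reactionTimeMs reaction delay.
#' @param feedbackDelayMs visuomotor feedback delay (default 160 ms):
#'   commands are computed from the cursor position this long ago, which is
#'   what makes decoder gain mismatches behaviorally costly (overshoot).
#' @param maxSpeed command saturation (%/s).
#' @return an [IntentionModel-class].
#' @export
intentionModel <- function(gain = 4, noiseSd = 4, reaimOffset = 0,
                           reactionTimeMs = 160, feedbackDelayMs = 160,
                           maxSpeed = 200) {
  new("IntentionModel", gain = gain, noiseSd = noiseSd,
      reaimOffset = as.numeric(reaimOffset),
      reactionTimeMs = reactionTimeMs, feedbackDelayMs = feedbackDelayMs,
      maxSpeed = maxSpeed)
}

#' Run a closed-loop BMI simulation
#'
#' Per 32 ms step the intention model emits a desired velocity toward the
#' current target (after its reaction time, with optional re-aim offset
#' and noise), the encoder maps `[cursor position, desired velocity, 1]`
#' to features (with the trial context's gain applied to flexor-linked
#' channels), and the Kalman decoder updates the cursor. A trial succeeds
#' after `holdMs` of continuous time in the target and fails at
#' `timeoutMs`.
#'
#' @param encoder a [linearEncoder()].
#' @param intention an [IntentionModel-class].
#' @param decoder a fitted [KalmanDecoder-class].
#' @param nTrials number of trials.
#' @param contextSchedule per-trial context labels (recycled), or a single
#'   label.
#' @param contextGains named per-context gains applied to flexor-linked
#'   encoder channels (default: all 1 except what the caller supplies).
#' @param task `"1dof"` or `"2dof"`.
#' @param holdMs,timeoutMs,targetWidth task constants (500 ms, 10 s, 15%).
#' @param seed RNG seed.
#' @return list: `results` (per-trial data.frame with metrics from
#'   [onlineMetrics()]), `trajectories`, `velocities`, `features`,
#'   `targets` (per-trial), `contexts`.
#' @export
simulateClosedLoop <- function(encoder, intention, decoder, nTrials = 100L,
                               contextSchedule = "normal",
                               contextGains = c(normal = 1),
                               task = "1dof", holdMs = 500,
                               timeoutMs = 10000, targetWidth = 15,
                               seed = 1L) {
  ctxOfTrial <- rep(contextSchedule, length.out = nTrials)
  dt <- decoder@binWidthMs / 1000
  holdSteps <- ceiling(holdMs / decoder@binWidthMs)
  maxSteps <- ceiling(timeoutMs / decoder@binWidthMs)
  reactSteps <- round(intention@reactionTimeMs / decoder@binWidthMs)
  delaySteps <- round(intention@feedbackDelayMs / decoder@binWidthMs)

  .withSeed(seed, "closed-loop", {
    cur <- c(50, 50)
    presentCenter <- FALSE
    results <- list(); trajectories <- list(); velocities <- list()
    featuresL <- list(); targetsL <- list()
    for (i in seq_len(nTrials)) {
      tgt <- if (presentCenter) c(50, 50) else .drawOutTarget(task)
      gain <- contextGains[[ctxOfTrial[i]]] %||% 1
      start <- cur
      kf <- kalmanInit(start)
      traj <- matrix(NA_real_, maxSteps, 2)
      vels <- matrix(NA_real_, maxSteps, 2)
      feats <- matrix(NA_real_, maxSteps, nrow(encoder$C))
      inARow <- 0L; done <- FALSE; success <- FALSE; step <- 0L
      while (!done && step < maxSteps) {
        step <- step + 1L
        pos <- kf$state[1:2]
        # the subject sees a delayed cursor and extrapolates it forward
        # with the seen velocity (visuomotor forward model); a decoder
        # gain mismatch corrupts this prediction and causes overshoot
        if (step - delaySteps >= 1) {
          sp0 <- traj[step - delaySteps, ]
          sv0 <- vels[step - delaySteps, ]
          seenPos <- sp0 + sv0 * delaySteps * dt
        } else seenPos <- start
        vDes <- c(0, 0)
        if (step > reactSteps) {
          toT <- tgt - seenPos
          dist <- sqrt(sum(toT^2))
          unit <- if (dist > 0) toT / dist else c(0, 0)
          sp <- min(intention@maxSpeed, intention@gain * dist)
          vDes <- unit * sp + unit * sum(intention@reaimOffset) +
            stats::rnorm(2, sd = intention@noiseSd)
        }
        f <- .encodeFeatures(encoder, c(pos, vDes, 1), gain)
        kf <- kalmanStep(decoder, kf$state, kf$P, f)
        traj[step, ] <- kf$position
        vels[step, ] <- kf$state[3:4]
        feats[step, ] <- f
        inside <- all(abs(kf$position - tgt) <= targetWidth / 2)
        inARow <- if (inside) inARow + 1L else 0L
        if (inARow >= holdSteps) { done <- TRUE; success <- TRUE }
      }
      traj <- traj[seq_len(step), , drop = FALSE]
      vels <- vels[seq_len(step), , drop = FALSE]
      feats <- feats[seq_len(step), , drop = FALSE]
      m <- onlineMetrics(traj, tgt, holdMs, startPos = start,
                         binWidthMs = decoder@binWidthMs,
                         targetWidth = targetWidth, success = success)
      results[[i]] <- cbind(data.frame(trial = i, context = ctxOfTrial[i],
                                       success = success,
                                       flexion = mean(tgt) > mean(start)),
                            as.data.frame(m))
      trajectories[[i]] <- traj
      velocities[[i]] <- vels
      featuresL[[i]] <- feats
      targetsL[[i]] <- tgt
      cur <- kf$position
      presentCenter <- if (success) !presentCenter else TRUE
    }
    list(results = do.call(rbind, results), trajectories = trajectories,
         velocities = velocities, features = featuresL,
         targets = targetsL, contexts = ctxOfTrial)
  })
}

#' Online performance metrics of one trial
#'
#' Acquisition time is the time from target presentation to trial end
#' minus the hold time; time to target is the first moment all fingers
#' with targets are inside them; orbiting time is their difference (zero
#' for trials that reach the target and never leave); path efficiency is
#' the straight-line start-to-target distance divided by the path length
#' traveled. For failed (timed-out) trials acquisition spans the full
#' trial and no hold is subtracted.
#'
#' @param trajectory steps x 2 matrix of cursor positions (32 ms).
#' @param target length-2 target center.
#' @param holdMs hold time.
#' @param startPos trial starting position.
#' @param binWidthMs sampling interval of the trajectory.
#' @param targetWidth target width (percent of range).
#' @param success logical trial outcome.
#' @return one-row data.frame: `acquisition_time_ms`, `time_to_target_ms`,
#'   `orbiting_time_ms`, `path_efficiency`.
#' @export
onlineMetrics <- function(trajectory, target, holdMs, startPos,
                          binWidthMs = 32L, targetWidth = 15,
                          success = TRUE) {
  nSteps <- nrow(trajectory)
  endMs <- nSteps * binWidthMs
  inside <- apply(abs(sweep(trajectory, 2, target)) <= targetWidth / 2, 1, all)
  firstIn <- which(inside)[1]
  # entry happens during the first inside bin, i.e. at its start
  ttt <- if (is.na(firstIn)) NA_real_ else (firstIn - 1) * binWidthMs
  # the realized hold is a whole number of bins
  holdRealized <- ceiling(holdMs / binWidthMs) * binWidthMs
  acq <- if (success) endMs - holdRealized else endMs
  orb <- if (success) acq - ttt else NA_real_
  seg <- diff(rbind(startPos, trajectory))
  pathLen <- sum(sqrt(rowSums(seg^2)))
  straight <- sqrt(sum((target - startPos)^2))
  data.frame(acquisition_time_ms = acq, time_to_target_ms = ttt,
             orbiting_time_ms = orb,
             path_efficiency = if (pathLen > 0) straight / pathLen else NA_real_)
}

#' Early-trial adaptation statistics
#'
#' Z-scores acquisition times within each context block (series), averages
#' the first `k` trials of every block, and tests the per-block scores:
#' one-sample Kolmogorov-Smirnov against the null of no early slowdown
#' (mean-zero normal with sd `1/sqrt(k)`), and two-sample KS comparing
#' normal versus off-context blocks.
#'
#' @param acquisitionMs per-trial acquisition times (failed trials
#'   included).
#' @param blockLabels per-trial block identifier.
#' @param contexts per-trial context label.
#' @param k number of early trials (default 5).
#' @return list: `perBlock` data.frame (block, context, earlyScore),
#'   `ksOneSample`, `ksTwoSample` (NULL when only one context present).
#' @export
adaptationStats <- function(acquisitionMs, blockLabels, contexts, k = 5L) {
  blocks <- unique(blockLabels)
  rows <- list()
  for (b in blocks) {
    sel <- which(blockLabels == b)
    if (length(sel) < k) {
      .warnf("adaptationStats: block %s shorter than k = %d, skipped", b, k)
      next
    }
    a <- acquisitionMs[sel]
    z <- if (stats::sd(a) > 0) (a - mean(a)) / stats::sd(a) else rep(0, length(a))
    rows[[length(rows) + 1L]] <- data.frame(
      block = b, context = contexts[sel[1]], earlyScore = mean(z[seq_len(k)]))
  }
  perBlock <- do.call(rbind, rows)
  if (is.null(perBlock) || !nrow(perBlock))
    .stopf("adaptationStats: no block long enough")
  ks1 <- compareGroups(perBlock$earlyScore, kind = "ks_one_sample",
                       null_sd = 1 / sqrt(k))
  isOff <- perBlock$context != "normal"
  ks2 <- if (any(isOff) && any(!isOff))
    compareGroups(perBlock$earlyScore[!isOff], perBlock$earlyScore[isOff],
                  kind = "ks_two_sample") else NULL
  list(perBlock = perBlock, ksOneSample = ks1, ksTwoSample = ks2)
}

#' ReFIT retraining from a closed-loop run
#'
#' Convenience wrapper assembling the per-bin matrices of a
#' [simulateClosedLoop()] run and calling [refitRetrain()].
#'
#' @param decoder the [KalmanDecoder-class] used in the run.
#' @param run result of [simulateClosedLoop()].
#' @param targetWidth target width used for the in-target rule.
#' @return retrained [KalmanDecoder-class].
#' @export
refitFromRun <- function(decoder, run, targetWidth = 15) {
  feats <- do.call(rbind, run$features)
  pos <- do.call(rbind, run$trajectories)
  vel <- do.call(rbind, run$velocities)
  tgt <- do.call(rbind, lapply(seq_along(run$targets), function(i)
    matrix(run$targets[[i]], nrow(run$trajectories[[i]]), 2, byrow = TRUE)))
  inT <- rowSums(abs(pos - tgt) <= targetWidth / 2) == 2
  refitRetrain(decoder, feats, pos, vel, tgt, inT)
}
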