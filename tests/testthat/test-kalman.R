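test_that("Kalman fitting recovers a linear observation model", {
  set.seed(53)
  n <- 600
  kin <- cbind(50 + cumsum(rnorm(n, sd = 0.1)),
               50 + cumsum(rnorm(n, sd = 0.1)),
               rnorm(n, sd = 20), rnorm(n, sd = 20))
  Cstar <- matrix(rnorm(12 * 5, sd = 0.05), 12, 5)
  feats <- cbind(kin, 1) %*% t(Cstar)      # noiseless observations
  kd <- fitKalman(feats, kin)
  expect_equal(kd@C, Cstar, tolerance = 1e-6, ignore_attr = TRUE)
  # constant-1 state row is fixed
  expect_equal(kd@A[5, ], c(0, 0, 0, 0, 1))
  # position rows implement physical integration
  expect_equal(kd@A[1:2, ], cbind(diag(2), 0.032 * diag(2), c(0, 0)),
               ignore_attr = TRUE)
  # velocity identically zero: velocity columns of C get zero weight
  kin0 <- kin; kin0[, 3:4] <- 0
  kd0 <- fitKalman(cbind(kin0, 1) %*% t(Cstar), kin0)
  expect_true(all(abs(kd0@C[, 3:4]) < 1e-8))
  expect_error(fitKalman(feats[1:4, ], kin[1:4, ]), "fewer samples")
})

test_that("the Kalman recursion matches a textbook reference filter", {
  set.seed(59)
  enc <- linearEncoder(16, seed = 3, noiseSd = 0.2)
  td <- simulateTrainingData(enc, 100, seed = 3)
  kd <- fitKalman(td$features, td$kinematics)
  obs <- td$features[1:1000, ]
  init <- kalmanInit(c(50, 50))
  # run both recursions side by side; the deployed protocol's post-step
  # (position from integrated velocity, constant reset) is applied
  # identically to the reference so the predict/update core is compared
  st <- init$state; P <- init$P
  rx <- init$state; rP <- init$P
  dt <- kd@binWidthMs / 1000
  maxdiff <- 0
  for (t in seq_len(nrow(obs))) {
    stp <- kalmanStep(kd, st, P, obs[t, ])
    ref <- referenceKalmanStep(kd@A, kd@W, kd@C, kd@Q, rx, rP, obs[t, ])
    refState <- ref$x
    refState[5] <- 1
    refState[1:2] <- pmin(pmax(rx[1:2] + refState[3:4] * dt, 0), 100)
    maxdiff <- max(maxdiff, max(abs(stp$state - refState)),
                   max(abs(stp$P - ref$P)))
    st <- stp$state; P <- stp$P
    rx <- refState; rP <- ref$P
  }
  expect_lt(maxdiff, 1e-10)

  # Q -> infinity: the Kalman gain vanishes and the posterior equals the
  # prior prediction
  kdBig <- kd
  kdBig@Q <- kd@Q + diag(1e12, nrow(kd@Q))
  init <- kalmanInit(c(40, 60))
  s1 <- kalmanStep(kdBig, c(40, 60, 5, -5, 1), init$P, obs[1, ])
  pred <- drop(kd@A %*% c(40, 60, 5, -5, 1))
  expect_equal(s1$state[3:4], pred[3:4], tolerance = 1e-4)

  # constant-velocity integration: position advances v * dt and clamps
  s2 <- kalmanStep(kdBig, c(99.9, 50, 100, 0, 1), init$P, obs[1, ])
  expect_equal(s2$position[2], 50, tolerance = 0.2)
  expect_lte(s2$position[1], 100)
  # non-finite features: step rejected, state held
  s3 <- kalmanStep(kd, c(50, 50, 3, 0, 1), init$P, c(NaN, obs[1, -1]))
  expect_true(s3$rejected)
  expect_equal(s3$state, c(50, 50, 3, 0, 1))
})

test_that("ReFIT rotation preserves speed and zeroes in-target velocity", {
  # decoded velocity (1,0) with target direction (0,1) -> intention (0,1)
  r <- rotateToTarget(matrix(c(1, 0), 1), matrix(c(0, 2), 1))
  expect_equal(drop(r), c(0, 1))
  # velocity already toward target: unchanged
  r2 <- rotateToTarget(matrix(c(3, 4), 1), matrix(c(3, 4) * 10, 1))
  expect_equal(drop(r2), c(3, 4))
  # magnitudes preserved exactly for random inputs
  set.seed(61)
  V <- matrix(rnorm(200), 100, 2)
  D <- matrix(rnorm(200), 100, 2)
  R <- rotateToTarget(V, D)
  expect_equal(sqrt(rowSums(R^2)), sqrt(rowSums(V^2)), tolerance = 1e-12)

  # full retraining: in-target bins get zero intention; A and W untouched
  enc <- linearEncoder(16, seed = 3, noiseSd = 0.2)
  td <- simulateTrainingData(enc, 80, seed = 3)
  kd <- fitKalman(td$features, td$kinematics)
  run <- simulateClosedLoop(enc, intentionModel(), kd, nTrials = 20,
                            seed = 5)
  rf <- refitFromRun(kd, run)
  expect_identical(rf@A, kd@A)
  expect_identical(rf@W, kd@W)
  expect_false(identical(rf@C, kd@C))
  expect_error(refitRetrain(kd, td$features[1:5, ], matrix(50, 5, 2),
                            matrix(0, 5, 2), matrix(NA_real_, 5, 2),
                            rep(FALSE, 5)),
               "no bins")
})

test_that("the closed loop is well-posed and degrades under planted mismatch", {
  enc <- linearEncoder(48, seed = 5, noiseSd = 0.3)
  td <- simulateTrainingData(enc, 200, seed = 5)
  kd <- fitKalman(td$features, td$kinematics)

  # matched encoder/decoder, low noise: near-ideal control
  run <- simulateClosedLoop(enc, intentionModel(noiseSd = 1), kd,
                            nTrials = 100, task = "1dof", seed = 9)
  r <- run$results
  expect_gte(mean(r$success), 0.95)
  expect_gt(mean(r$path_efficiency[r$success]), 0.9)

  # near-zero intention gain: no out-target acquisitions (center trials,
  # where the cursor already starts inside, are the only trivial passes)
  run0 <- simulateClosedLoop(enc, intentionModel(gain = 1e-9), kd,
                             nTrials = 10, task = "1dof", seed = 9)
  outT <- vapply(run0$targets, function(tg) any(tg != 50), logical(1))
  expect_equal(mean(run0$results$success[outT]), 0)

  # planted context gain on flexor-linked channels slows flexion targets
  run2 <- simulateClosedLoop(enc, intentionModel(noiseSd = 8), kd,
                             nTrials = 200,
                             contextSchedule = rep(c("normal", "spring"),
                                                   each = 4),
                             contextGains = c(normal = 1, spring = 1.9),
                             task = "1dof", seed = 7)
  r2 <- run2$results
  ok <- r2$success & r2$flexion
  a <- r2$acquisition_time_ms[ok & r2$context == "normal"]
  b <- r2$acquisition_time_ms[ok & r2$context == "spring"]
  expect_lt(t.test(b, a, alternative = "greater")$p.value, 0.05)
})

test_that("online metrics satisfy their defining identities", {
  # straight constant-velocity path to the target, then a full hold,
  # never exits
  approach <- cbind(seq(52, 90, by = 2), seq(51, 70, by = 1))[1:16, ]
  traj <- rbind(approach, matrix(c(90, 70), 16, 2, byrow = TRUE))
  m <- onlineMetrics(traj, c(90, 70), holdMs = 500, startPos = c(50, 50),
                     success = TRUE)
  expect_equal(m$path_efficiency, 1, tolerance = 1e-9)
  expect_equal(m$orbiting_time_ms, 0)
  expect_equal(m$acquisition_time_ms, m$time_to_target_ms)
  # a path twice the straight distance scores 0.5
  zig <- rbind(cbind(seq(50, 90, length.out = 21), 50),
               cbind(seq(90, 50, length.out = 20), 50),
               cbind(seq(50, 90, length.out = 20), 50))
  m2 <- onlineMetrics(zig, c(90, 50), holdMs = 0, startPos = c(50, 50),
                      success = TRUE)
  expect_equal(m2$path_efficiency, (40) / (40 * 3), tolerance = 0.05)
  # random walks are never perfectly straight
  set.seed(67)
  eff <- replicate(100, {
    rw <- apply(matrix(rnorm(100, sd = 2), 50, 2), 2, cumsum) + 50
    onlineMetrics(rw, c(90, 90), holdMs = 0, startPos = c(50, 50),
                  success = FALSE)$path_efficiency
  })
  expect_true(all(eff < 1))
  # acquisition = time to target + orbiting on successful simulated trials
  enc <- linearEncoder(16, seed = 3, noiseSd = 0.3)
  td <- simulateTrainingData(enc, 100, seed = 3)
  kd <- fitKalman(td$features, td$kinematics)
  run <- simulateClosedLoop(enc, intentionModel(noiseSd = 10), kd,
                            nTrials = 40, seed = 13)
  r <- run$results[run$results$success, ]
  expect_equal(r$acquisition_time_ms,
               r$time_to_target_ms + r$orbiting_time_ms)
})

test_that("adaptation statistics are calibrated and detect planted slowdowns", {
  set.seed(71)
  # null: i.i.d. acquisition times -> rejection near the nominal level
  rej <- replicate(200, {
    a <- rexp(200, rate = 1 / 800)
    blocks <- rep(1:10, each = 20)
    ctx <- rep(c("normal", "spring"), each = 100)
    adaptationStats(a, blocks, ctx)$ksOneSample$p < 0.05
  })
  expect_gt(mean(rej), 0.005); expect_lt(mean(rej), 0.15)
  # planted 2-sd slowdown on the first five trials of every block
  a <- rnorm(400, 800, 100)
  blocks <- rep(1:20, each = 20)
  idx <- outer(1:5, (0:19) * 20, `+`)
  a[idx] <- a[idx] + 200
  st <- adaptationStats(a, blocks, rep("normal", 400))
  expect_lt(st$ksOneSample$p, 0.01)
  expect_gt(mean(st$perBlock$earlyScore), 0)
  # constant times in a block: z-scores collapse to zero
  st0 <- adaptationStats(rep(700, 30), rep(1, 30), rep("normal", 30))
  expect_equal(st0$perBlock$earlyScore, 0)
  expect_warning(adaptationStats(rnorm(7, 800), c(rep(1, 5), 2, 2),
                                 rep("normal", 7), k = 5),
                 "shorter")
})
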