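cfg24 <- generatorConfig(seed = 7L, nChannels = 24L)

test_that("minimum-jerk kinematics match their closed forms", {
  # peak speed of a minimum-jerk reach is 15 A / (8 T)
  kin <- makeKinematics(c(90, 90), c(50, 50), cfg24, reactionMs = 100,
                        holdMs = 200)
  expect_equal(max(kin$velocity[, 1]), 15 * 40 / (8 * 0.5),
               tolerance = 1e-3)
  # zero-amplitude movement: constant position, zero velocity
  kin0 <- makeKinematics(c(50, 50), c(50, 50), cfg24)
  expect_true(all(kin0$velocity == 0))
  expect_true(all(kin0$position == 50))
  # a 40% flexion from center ends (and holds) at 90
  expect_equal(tail(kin$position[, 1], 1), 90, tolerance = 1e-9)
})

test_that("muscle envelopes follow the context gain model", {
  kin <- makeKinematics(c(90, 90), c(50, 50), cfg24)
  gr <- muscleGroups()
  # normal context, pure flexion: extensors stay at baseline
  envN <- makeMuscleActivity(kin, "normal", cfg24)$envelope
  expect_true(all(abs(envN[, gr$extensor] - cfg24@emgBaseline) < 1e-12))
  # zero velocity everywhere: all muscles at baseline
  kin0 <- makeKinematics(c(50, 50), c(50, 50), cfg24)
  env0 <- makeMuscleActivity(kin0, "spring", cfg24)$envelope
  expect_true(all(abs(env0 - cfg24@emgBaseline) < 1e-12))
  # spring flexion: flexors scale by the gain, extensors co-contract
  envS <- makeMuscleActivity(kin, "spring", cfg24)$envelope
  expect_equal(max(envS[, gr$flexor] - cfg24@emgBaseline),
               1.92 * max(envN[, gr$flexor] - cfg24@emgBaseline),
               tolerance = 1e-9)
  expect_gt(max(envS[, gr$extensor]), cfg24@emgBaseline)
  expect_error(makeMuscleActivity(kin, "zero-g", cfg24), "unknown context")
})

test_that("spring flexor gain is recovered by the peri-movement statistic", {
  s <- smallSession()
  tr <- selectAnalysisTrials(s)
  kv <- savgolVelocity(streams(s)@fingerPosition)
  emg <- gaussianSmooth(muscleActivations(s, 20L))
  base <- s@groundTruth$config@emgBaseline
  periFlex <- function(ctx) {
    rows <- tr[tr$context == ctx & tr$target_center_index > 50, ]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      pk <- findPeakMovement(kv$velocity, rows$presentation_time_ms[i],
                             rows$end_time_ms[i])
      mean(periMovementAverage(emg, pk$peakBinIndex)[muscleGroups()$flexor])
    }, numeric(1)))
  }
  ratio <- (periFlex("spring") - base) / (periFlex("normal") - base)
  expect_equal(ratio, 1.92, tolerance = 0.05 * 1.92)
})

test_that("raw EMG is band-limited noise whose binned MAV recovers the envelope", {
  kin <- makeKinematics(c(90, 90), c(50, 50), cfg24, reactionMs = 100,
                        holdMs = 400)
  ma <- makeMuscleActivity(kin, "normal", cfg24, raw = TRUE)
  env <- emgEnvelope(ma$raw, binWidthMs = 50L)
  got <- unname(featureValues(env)[, 2])
  want <- unname(colMeans(matrix(ma$envelope[, 2],
                                 nrow = 50))[seq_along(got)])
  # re-filtering the modulated carrier shrinks it by a uniform factor and
  # smears it slightly; recovery is therefore judged as proportionality
  # (every gain-based analysis uses ratios, where a common factor cancels)
  keep <- -(1:2)                          # filter warm-up bins
  ratio <- mean(got[keep]) / mean(want[keep])
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.1)
  expect_gt(stats::cor(got[keep], want[keep]), 0.9)
  rel <- got[keep] / want[keep]
  expect_lt(stats::sd(rel) / mean(rel), 0.2)
})

test_that("latent groups have the planted structure", {
  kin <- makeKinematics(c(90, 90), c(50, 50), cfg24)
  mkEnv <- function(ctx) makeMuscleActivity(kin, ctx, cfg24)$envelope
  groups <- cfg24@latentGroups

  # normal context: context-group latents are identically zero
  zN <- makeLatents(kin, mkEnv("normal"), cfg24)$z
  expect_true(all(zN[, groups >= 3] == 0))

  # two contexts differing only in flexor gain (no co-contraction):
  # context-latent amplitudes scale as the gain deviation from normal,
  # (g1 - 1) / (g2 - 1), by the difference construction
  cfgNc <- generatorConfig(seed = 7L, nChannels = 24L,
                           cocontractionGain = c(normal = 0, spring = 0,
                                                 wrist = 0, band = 0,
                                                 both = 0))
  mkEnvNc <- function(ctx) makeMuscleActivity(kin, ctx, cfgNc)$envelope
  zS <- makeLatents(kin, mkEnvNc("spring"), cfgNc)$z
  zW <- makeLatents(kin, mkEnvNc("wrist"), cfgNc)$z
  cxCol <- which(groups == 3)[1]
  ratio <- max(zS[, cxCol]) / max(zW[, cxCol])
  expect_equal(ratio, (1.92 - 1) / (1.53 - 1), tolerance = 1e-6)

  # flexion vs extension: target latents flip sign
  kinE <- makeKinematics(c(10, 10), c(50, 50), cfg24)
  zF <- makeLatents(kin, mkEnv("normal"), cfg24)$z
  zE <- makeLatents(kinE, makeMuscleActivity(kinE, "normal", cfg24)$envelope,
                    cfg24)$z
  velCol <- which(groups == 2)[2]
  expect_equal(zE[, velCol], -zF[, velCol], tolerance = 1e-9)
})

test_that("the neural observation model is deterministic and Poisson-calibrated", {
  z <- matrix(0, 2000, cfg24@nLatents)
  n1 <- makeNeural(list(z = z, groups = cfg24@latentGroups), cfg24)
  n2 <- makeNeural(list(z = z, groups = cfg24@latentGroups), cfg24)
  expect_identical(n1$sbp1ms, n2$sbp1ms)
  expect_identical(n1$crossingTimes, n2$crossingTimes)
  expect_true(all(n1$rawSampleCount1ms == 2L))

  # constant-drive channel: empirical crossing rate within 3 SE of the
  # softplus rate over a long stretch
  cfgQuiet <- generatorConfig(seed = 7L, nChannels = 24L, noiseSdSbp = 1e-9)
  nsec <- 100
  zz <- matrix(0, nsec * 1000, cfgQuiet@nLatents)
  nn <- makeNeural(list(z = zz, groups = cfgQuiet@latentGroups), cfgQuiet)
  base <- fingerctx:::.channelBaseline(cfgQuiet)
  for (ch in c(1, 13)) {
    lambda <- cfgQuiet@rateScaleHz * log1p(exp(base[ch]))
    nEvents <- length(nn$crossingTimes[[ch]])
    se <- sqrt(lambda * nsec)
    expect_lt(abs(nEvents - lambda * nsec), 3 * se)
  }
})

test_that("generated sessions respect the task protocol", {
  s <- smallSession()
  tr <- trials(s)
  # contexts match the block schedule
  expect_identical(unique(tr$context[s@contextBlockLabels == 1]), "normal")
  expect_identical(unique(tr$context[s@contextBlockLabels == 2]), "spring")
  # 1-DOF: every non-center target is at +/-40% from center
  out <- tr$target_center_index[tr$target_center_index != 50]
  expect_true(all(out %in% c(10, 90)))
  # center is re-presented after any failed trial
  failed <- which(!tr$success)
  failed <- failed[failed < nrow(tr)]
  expect_true(all(tr$target_center_index[failed + 1] == 50))
  expect_error(generateSession(s@groundTruth$config, character(0)),
               "empty context schedule")
})

test_that("a noise-dominated configuration yields no modulated channels", {
  cfg <- generatorConfig(seed = 17L, nChannels = 24L, noiseSdSbp = 40,
                         trialsPerBlock = c(20L, 20L))
  s <- generateSession(cfg, c("normal", "spring"), task = "1dof")
  res <- tuningAnalysis(s, "sbp")
  expect_lte(res$nModulated, 1L)
})

test_that("generator configurations round-trip through YAML", {
  cfg <- generatorConfig(seed = 9L, nChannels = 24L, noiseSdSbp = 0.4,
                         trialsPerBlock = c(30L, 45L))
  f <- file.path(tempdir(), "genconfig.yaml")
  on.exit(unlink(f))
  writeGeneratorConfig(cfg, f)
  cfg2 <- readGeneratorConfig(f)
  expect_equal(cfg2@latentLoading, cfg@latentLoading)
  expect_identical(cfg2@trialsPerBlock, cfg@trialsPerBlock)
  expect_equal(cfg2@contextGainFlexor, cfg@contextGainFlexor)
  expect_equal(cfg2@noiseSdSbp, 0.4)
})
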