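test_that("the lagged design matches a loop oracle and drops warm-up rows", {
  set.seed(37)
  V <- matrix(rnorm(40 * 2), 40, 2)
  tid <- rep(1:2, each = 20)
  lag <- buildLaggedDesign(V, tid, 3L)
  # 2 channels, history 12: 2 x 13 = 26 columns (+1 intercept downstream)
  expect_identical(ncol(buildLaggedDesign(V, tid, 12L)$X), 26L)
  expect_identical(ncol(lag$X), 8L)
  # loop oracle for row contents
  for (r in sample(seq_along(lag$rows), 5)) {
    row <- lag$rows[r]
    want <- c(V[row, ], V[row - 1, ], V[row - 2, ], V[row - 3, ])
    expect_equal(lag$X[r, ], want)
  }
  # no cross-trial leakage: first 3 rows of each trial dropped
  expect_false(any(lag$rows %in% c(1:3, 21:23)))
  # history 0: design equals the features
  lag0 <- buildLaggedDesign(V, tid, 0L)
  expect_equal(lag0$X, V)
  expect_warning(buildLaggedDesign(V[1:5, ], rep(1, 5), 12L), "skipped")
})

test_that("ridge at lambda 0 equals an independent normal-equations solve", {
  set.seed(41)
  X <- matrix(rnorm(200 * 10), 200, 10)
  Y <- cbind(X %*% rnorm(10) + rnorm(200), X %*% rnorm(10))
  fit <- fitRidge(X, Y, 0)
  # independent oracle: ordinary least squares with explicit intercept
  Xi <- cbind(X, 1)
  oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% Y)
  expect_equal(unname(fit$weights), unname(oracle), tolerance = 1e-8)

  # lambda -> infinity: slopes vanish, prediction -> training mean
  fitBig <- fitRidge(X, Y, 1e12)
  expect_lt(max(abs(fitBig$weights[1:10, ])), 1e-6)
  expect_equal(unname(fitBig$weights[11, ]), unname(colMeans(Y)),
               tolerance = 1e-6)

  # planted weights are recovered under light noise
  Wstar <- matrix(rnorm(10 * 2), 10, 2)
  Yp <- X %*% Wstar + matrix(rnorm(400, sd = 1e-4), 200, 2)
  fitP <- fitRidge(X, Yp, 0)
  expect_equal(unname(fitP$weights[1:10, ]), unname(Wstar),
               tolerance = 1e-2)

  expect_error(fitRidge(X[1:5, ], Y[1:5, ], 0), "singular")
})

test_that("prediction metrics satisfy their algebraic identities", {
  set.seed(43)
  m <- rnorm(500, mean = 3, sd = 2)
  # constant-mean predictor -> nMSE exactly 1
  pm <- predictionMetrics(rep(mean(m), 500), m)
  expect_identical(pm$nmse, 1)
  # perfect predictor -> nMSE 0, r 1
  pp <- predictionMetrics(m, m)
  expect_equal(pp$nmse, 0); expect_equal(pp$r, 1)
  # sign-flipped predictor: r = -1, nMSE from the algebraic expansion
  centered <- m - mean(m)
  pf <- predictionMetrics(-m, m)
  expect_equal(pf$r, -1)
  oracleNmse <- mean((m - (-m))^2) / mean(centered^2)
  expect_equal(pf$nmse, oracleNmse, tolerance = 1e-12)
  # nMSE == 1 - R^2 on 100 random test sets
  for (i in 1:100) {
    meas <- rnorm(60); pred <- 0.5 * meas + rnorm(60)
    got <- predictionMetrics(pred, meas)$nmse
    r2 <- 1 - sum((meas - pred)^2) / sum((meas - mean(meas))^2)
    expect_lt(abs(got - (1 - r2)), 1e-10)
  }
  expect_error(predictionMetrics(rnorm(5), rep(2, 5)), "zero variance")
})

test_that("cross-context decoding detects planted gain changes and nulls cleanly", {
  s <- smallSession()      # normal + spring at default gains
  cv <- crossvalGeneralization(s, "emg_envelope", ridgeLambda = 10)
  flex <- paste0("y", muscleGroups()$flexor)
  pf <- cv$perFold
  nm <- pf[pf$test_set == "normal_heldout" & pf$output %in% flex, ]
  sp <- pf[pf$test_set == "spring" & pf$output %in% flex, ]
  nmM <- aggregate(nmse ~ fold, nm, mean)$nmse
  spM <- aggregate(nmse ~ fold, sp, mean)$nmse
  # off-context flexor error inflates significantly (paired across folds)
  expect_lt(t.test(spM, nmM, paired = TRUE, alternative = "greater")$p.value,
            0.01)
  # within-context decoding is good in absolute terms
  expect_lt(mean(nmM), 0.5)
  # fold assignment is deterministic: identical metrics on a rerun
  cv2 <- crossvalGeneralization(s, "emg_envelope", ridgeLambda = 10)
  expect_identical(cv$perFold$nmse, cv2$perFold$nmse)

  # null generator (all gains 1): off-context nMSE within the fold-to-fold
  # spread of the held-out normal nMSE
  cfg0 <- generatorConfig(seed = 47L, nChannels = 32L,
                          trialsPerBlock = c(30L, 30L),
                          contextGainFlexor = c(normal = 1, spring = 1,
                                                wrist = 1, band = 1, both = 1),
                          contextGainExtensor = c(normal = 1, spring = 1,
                                                  wrist = 1, band = 1,
                                                  both = 1),
                          cocontractionGain = c(normal = 0, spring = 0,
                                                wrist = 0, band = 0, both = 0))
  s0 <- generateSession(cfg0, c("normal", "spring"), task = "1dof")
  cv0 <- crossvalGeneralization(s0, "emg_envelope", ridgeLambda = 10)
  sm0 <- cv0$summary
  for (out in unique(sm0$output)) {
    a <- sm0[sm0$test_set == "normal_heldout" & sm0$output == out, ]
    b <- sm0[sm0$test_set == "spring" & sm0$output == out, ]
    expect_lt(abs(b$nmse - a$nmse), 3 * a$nmse_sd + 0.05)
  }
})

test_that("kinematic decoding works and training error is optimistic", {
  s <- smallSession()
  cv <- crossvalGeneralization(s, "kinematics", ridgeLambda = 10, folds = 5L)
  sm <- cv$summary
  velRows <- sm[sm$test_set == "normal_heldout" &
                  grepl("vel", sm$output), ]
  expect_true(all(velRows$nmse < 0.6))
  expect_true(all(velRows$r > 0.7))
  # GCV lambda selection runs and returns finite metrics
  cvG <- crossvalGeneralization(s, "kinematics", folds = 3L)
  expect_true(all(is.finite(cvG$perFold$nmse)))
  expect_true(all(cvG$lambda > 0))
})
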