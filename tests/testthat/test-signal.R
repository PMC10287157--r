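mkStreams <- function(sbp, cnt = NULL, crossings = NULL, pos = NULL) {
  n <- nrow(sbp); nc <- ncol(sbp)
  continuousStreams(
    sbp,
    if (is.null(cnt)) matrix(2L, n, nc) else cnt,
    if (is.null(crossings)) rep(list(numeric(0)), nc) else crossings,
    if (is.null(pos)) matrix(50, n, 2) else pos)
}

test_that("SBP binning implements the sum-over-count ratio", {
  # constant rectified amplitude a on every sample -> every bin = a
  st <- mkStreams(matrix(2 * 0.7, 64, 3))   # per-ms sum of two samples
  b <- binSBP(st, 32L)
  expect_true(all(abs(featureValues(b) - 0.7) < 1e-12))
  expect_identical(nrow(featureValues(b)), 2L)

  # random stream vs an independently coded loop oracle
  set.seed(5)
  sbp <- matrix(rexp(500 * 4), 500, 4)
  cnt <- matrix(sample(1:2, 2000, replace = TRUE), 500, 4)
  got <- featureValues(binSBP(mkStreams(sbp, cnt), 20L))
  oracle <- matrix(0, 25, 4)
  for (b_ in 1:25) for (ch in 1:4) {
    rows <- ((b_ - 1) * 20 + 1):(b_ * 20)
    oracle[b_, ch] <- sum(sbp[rows, ch]) / sum(cnt[rows, ch])
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # zero raw samples in a bin: value 0 with a warning
  cnt0 <- matrix(0L, 40, 1)
  expect_warning(b0 <- binSBP(mkStreams(matrix(1, 40, 1), cnt0), 20L),
                 "zero raw samples")
  expect_true(all(featureValues(b0) == 0))
})

test_that("TCFR binning counts events per bin in Hz", {
  # 3 events in one 20 ms bin -> 150 Hz
  b <- binTCFR(list(c(2, 7, 19)), 20L, 40L)
  expect_equal(featureValues(b)[, 1], c(150, 0))
  # empty channel -> all-zero bins
  expect_true(all(featureValues(binTCFR(list(numeric(0)), 20L, 100L)) == 0))
  # Poisson events at 30 Hz over 100 s: mean rate within 3 SE
  set.seed(8)
  ev <- cumsum(rexp(6000, rate = 30 / 1000))
  ev <- ev[ev < 1e5]
  rate <- mean(featureValues(binTCFR(list(ev), 50L, 100000L)))
  se <- sqrt(30 / 100)                    # SE of a Poisson rate over 100 s
  expect_lt(abs(rate - 30), 3 * se)
})

test_that("coincidence artifacts are removed at the 20-channel threshold", {
  base <- lapply(1:25, function(i) c(i * 3 + 0.5))
  # 19 coincident channels: nothing removed
  cr19 <- c(lapply(1:19, function(i) c(100.2)), base[1:5])
  expect_identical(removeArtifacts(cr19), cr19)
  # 20 coincident channels: that millisecond cleared everywhere
  cr20 <- c(lapply(1:20, function(i) c(100.2, 200 + i)), base[1:5])
  out <- removeArtifacts(cr20)
  expect_true(all(vapply(out[1:20], function(x) !any(floor(x) == 100),
                         logical(1))))
  expect_true(all(vapply(seq_len(20), function(i)
    any(out[[i]] == 200 + i), logical(1))))
  # planted artifacts at known ticks are removed exactly, and the
  # operation is idempotent
  set.seed(9)
  clean <- lapply(1:30, function(i) sort(sample(0:999, 40)) + 0.1)
  artTicks <- c(111, 502, 733)
  dirty <- lapply(clean, function(x) sort(c(x, artTicks + 0.4)))
  cleaned <- removeArtifacts(dirty)
  for (ch in 1:30)
    expect_equal(cleaned[[ch]], clean[[ch]][!(floor(clean[[ch]]) %in% artTicks)])
  expect_identical(removeArtifacts(cleaned), cleaned)
})

test_that("EMG envelope extraction matches analytic filter behavior", {
  t10 <- seq_len(20000) / 10000
  # passband sinusoid amplitude A: envelope ~ 2A/pi after the transient
  A <- 3
  emg <- matrix(A * sin(2 * pi * 300 * t10), ncol = 1)
  env <- featureValues(emgEnvelope(emg, 50L))
  expect_equal(mean(env[-(1:4), 1]), 2 * A / pi, tolerance = 0.05 * 2 * A / pi)
  # 10 Hz tone is attenuated more than 20x relative to passband
  emgLow <- matrix(A * sin(2 * pi * 10 * t10), ncol = 1)
  envLow <- featureValues(emgEnvelope(emgLow, 50L))
  expect_gt(mean(env[-(1:4), 1]) / mean(envLow[-(1:4), 1]), 20)
  # all-zero input -> all-zero envelope
  expect_true(all(featureValues(emgEnvelope(matrix(0, 10000, 2), 50L)) == 0))
  expect_error(emgEnvelope(matrix(0, 10, 1), 20L), "warm-up")
})

test_that("Gaussian smoothing is unit-sum, DC-preserving, and variance-calibrated", {
  mk <- function(values) new("BinnedFeatures", values = values,
    binWidthMs = 20L,
    binStartTimesMs = (seq_len(nrow(values)) - 1) * 20,
    channelMask = rep(TRUE, ncol(values)), featureKind = "sbp")
  # unit impulse -> kernel weights summing to 1
  imp <- matrix(0, 101, 1); imp[51] <- 1
  sm <- featureValues(gaussianSmooth(mk(imp)))
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  sigma <- 100 / 20
  half <- ceiling(3 * sigma)
  kern <- dnorm(seq(-half, half), sd = sigma); kern <- kern / sum(kern)
  expect_equal(sm[(51 - half):(51 + half), 1], kern, tolerance = 1e-9)
  # constant signal unchanged, including at the edges
  con <- featureValues(gaussianSmooth(mk(matrix(4.2, 60, 2))))
  expect_true(all(abs(con - 4.2) < 1e-9))
  # white-noise variance shrinks by the kernel's sum of squares
  set.seed(11)
  wn <- matrix(rnorm(20000), ncol = 2)
  smwn <- featureValues(gaussianSmooth(mk(wn)))
  inner <- (half + 1):(nrow(wn) - half)
  expect_equal(var(as.numeric(smwn[inner, ])), sum(kern^2),
               tolerance = 0.1)
  # the FWHM reading gives a narrower kernel
  smF <- featureValues(gaussianSmooth(mk(imp), interpretation = "fwhm"))
  expect_gt(max(smF), max(sm))
})

test_that("Savitzky-Golay velocities are exact on low-order polynomials", {
  t1 <- seq_len(3000)
  # linear ramp of slope m %/ms -> velocity 1000*m %/s everywhere interior
  m <- 0.01
  pos <- cbind(10 + m * t1, 10 + m * t1)
  kv <- savgolVelocity(pos)
  v <- featureValues(kv$velocity)
  expect_true(all(abs(v[4:(nrow(v) - 4), ] - m * 1000) < 1e-8))
  # quadratic trajectory: exact derivative interior
  a <- 1e-5
  posq <- cbind(10 + a * t1^2, 10 + a * t1^2)[1:2000, ]
  kvq <- savgolVelocity(posq)
  vq <- featureValues(kvq$velocity)
  binCenters <- (seq_len(nrow(vq)) - 1) * 20 + 10.5
  want <- 2 * a * binCenters * 1000
  inner <- 5:(nrow(vq) - 5)
  expect_equal(vq[inner, 1], want[inner], tolerance = 1e-6)
  # minimum-jerk closed form: peak speed within 2% of 15A/(8T) = 150 %/s
  mj <- cbind(minJerkPosition(40, 500), minJerkPosition(40, 500))
  mj <- rbind(matrix(mj[1, ], 200, 2, byrow = TRUE), mj,
              matrix(mj[nrow(mj), ], 300, 2, byrow = TRUE))
  kvm <- savgolVelocity(mj)
  expect_equal(max(featureValues(kvm$velocity)[, 1]), 150,
               tolerance = 0.02 * 150)
})

test_that("peak-movement detection follows the largest-local-peak rule", {
  mk <- function(v) new("BinnedFeatures", values = cbind(v, v),
    binWidthMs = 20L, binStartTimesMs = (seq_along(v) - 1) * 20,
    channelMask = c(TRUE, TRUE), featureKind = "kinematics")
  # single bump -> its apex
  bump <- dnorm(seq(-3, 3, length.out = 31))
  pk <- findPeakMovement(mk(bump))
  expect_identical(pk$peakBinIndex, 16L)
  expect_false(pk$degenerate)
  # two peaks, second larger -> second
  two <- c(dnorm(seq(-3, 3, length.out = 15)),
           2 * dnorm(seq(-3, 3, length.out = 15)))
  expect_identical(findPeakMovement(mk(two))$peakBinIndex, 23L)
  # monotone trace -> global max with the degenerate flag
  mono <- seq(0, 1, length.out = 20)
  pkm <- findPeakMovement(mk(mono))
  expect_true(pkm$degenerate)
  expect_identical(pkm$peakBinIndex, 20L)
  # minimum-jerk trial: peak at the movement midpoint within one bin
  mj <- cbind(minJerkPosition(40, 500), minJerkPosition(40, 500))
  mj <- rbind(matrix(50, 200, 2), mj, matrix(mj[nrow(mj), ], 300, 2,
                                             byrow = TRUE))
  kv <- savgolVelocity(mj)
  pkj <- findPeakMovement(kv$velocity, presentationTimeMs = 0)
  expect_lt(abs(pkj$peakTimeMs - (200 + 250)), 21)
})

test_that("peri-movement averaging matches a loop oracle", {
  mk <- function(values) new("BinnedFeatures", values = values,
    binWidthMs = 20L, binStartTimesMs = (seq_len(nrow(values)) - 1) * 20,
    channelMask = rep(TRUE, ncol(values)), featureKind = "sbp")
  # constant channel -> the constant; 21 bins at 20 ms = 420 ms
  con <- mk(matrix(3.3, 50, 2))
  expect_equal(unname(periMovementAverage(con, 25)), c(3.3, 3.3))
  expect_identical(21L * 20L, 420L)
  # random input vs loop oracle
  set.seed(13)
  x <- matrix(rnorm(50 * 3), 50, 3)
  got <- periMovementAverage(mk(x), 30, 10, 10)
  oracle <- vapply(1:3, function(ch) mean(x[20:40, ch]), numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  expect_error(periMovementAverage(mk(x), 5, 10, 10), "window")
})

test_that("group comparisons return the named classical tests", {
  set.seed(17)
  a <- rnorm(50)
  # identical groups: two-sample KS p = 1, t = 0
  expect_equal(compareGroups(a, a, "ks_two_sample")$p, 1)
  expect_equal(compareGroups(a, a, "two_sample_t")$statistic, 0)
  # a 10-sd shift separates overwhelmingly
  expect_lt(compareGroups(a, a + 10, "two_sample_t")$p, 1e-10)
  # two-sample CI covers a planted shift at ~99% over replicates
  covered <- vapply(1:300, function(i) {
    x <- rnorm(300); y <- rnorm(300) + 0.2
    ci <- compareGroups(x, y, "two_sample_t", ciLevel = 0.99)$ci
    ci[1] <= -0.2 && -0.2 <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.96)
  expect_error(compareGroups(rep(1, 5), rep(1, 5), "two_sample_t"),
               "degenerate")
})
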