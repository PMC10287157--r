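randomTensor <- function(N = 20, Cn = 3, Dn = 2, Tn = 30, seed = 109) {
  set.seed(seed)
  array(rnorm(N * Cn * Dn * Tn), c(N, Cn, Dn, Tn))
}

test_that("marginalized parts reconstruct the centered averages exactly", {
  X <- randomTensor()
  Xc <- X - c(apply(X, 1, mean))
  parts <- fingerctx:::.marginalize(Xc)
  expect_lt(max(abs(Xc - Reduce(`+`, parts))), 1e-10)
  # variance fractions sum to 1 on random tensors
  mv <- marginalizationVariance(X)
  expect_equal(sum(mv), 1, tolerance = 1e-6)
  # the parts are mutually orthogonal under the averaging inner product
  flat <- lapply(parts, as.numeric)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(sum(flat[[i]] * flat[[j]])) /
                sqrt(sum(flat[[i]]^2) * sum(flat[[j]]^2) + 1e-30), 1e-10)
})

test_that("pure structures land in their own marginalization", {
  N <- 15; Cn <- 3; Dn <- 2; Tn <- 25
  # pure condition-independent data: time fraction = 1
  tprof <- sin(seq_len(Tn) / 3)
  Xt <- aperm(array(outer(rnorm(N), tprof), c(N, Tn, Cn, Dn)), c(1, 3, 4, 2))
  mvT <- marginalizationVariance(Xt)
  expect_equal(unname(mvT["condition_independent"]), 1, tolerance = 1e-9)

  # planted target-only structure + isotropic noise: the target
  # marginalization holds essentially all non-noise variance and the
  # context components sit at the noise floor
  set.seed(113)
  U <- qr.Q(qr(matrix(rnorm(N * 2), N, 2)))
  Xd <- array(0, c(N, Cn, Dn, Tn))
  for (d in seq_len(Dn)) {
    sig <- (2 * d - 3) * outer(U[, d], sin(seq_len(Tn) / 4)) * 5
    for (cc in seq_len(Cn)) Xd[, cc, d, ] <- sig
  }
  noise <- array(rnorm(length(Xd), sd = 0.05), dim(Xd))
  mvD <- marginalizationVariance(Xd + noise)
  nonNoise <- mvD["target"] + mvD["condition_independent"]
  expect_gt(unname(mvD["target"] / (1 - mvD["condition_independent"])), 0.99)
  expect_lt(unname(mvD["context"]), 0.01)

  dp <- dpcaFit(Xd + noise, nComponents = 8)
  expect_true(sum(dp@componentMarg == "target") >= 2)
  vt <- sum(dp@varFractionComponent[dp@componentMarg == "target"])
  vc <- sum(dp@varFractionComponent[dp@componentMarg == "context"])
  expect_gt(vt, 50 * vc)
})

test_that("dPCA reconstructs marginalizations at least as well as a PCA basis", {
  X <- randomTensor(N = 18, Cn = 3, Dn = 2, Tn = 20, seed = 127)
  Xc <- X - c(apply(X, 1, mean))
  parts <- fingerctx:::.marginalize(Xc)
  Z <- matrix(Xc, 18)
  dp <- dpcaFit(X, nComponents = 8, regularization = 0)
  # PCA basis restricted to the same per-marginalization rank, with the
  # optimal regression inside that subspace
  sv <- svd(Z)
  for (m in unique(dp@componentMarg)) {
    q <- sum(dp@componentMarg == m)
    Zm <- matrix(parts[[m]], 18)
    Fd <- dp@encoder[, dp@componentMarg == m, drop = FALSE]
    Dd <- dp@decoder[dp@componentMarg == m, , drop = FALSE]
    errD <- sum((Zm - Fd %*% Dd %*% Z)^2)
    U <- sv$u[, seq_len(q), drop = FALSE]
    # best reconstruction of Zm through the rank-q PCA subspace
    B <- Zm %*% t(Z) %*% solve(Z %*% t(Z))
    errP <- sum((Zm - U %*% crossprod(U, B %*% Z))^2)
    expect_lte(errD, errP + 1e-8)
  }
})

test_that("the generated multi-context session has recoverable structure", {
  s <- multiCtxSession()
  tens <- buildTrialTensor(s)
  mv <- marginalizationVariance(tens)
  expect_equal(sum(mv), 1, tolerance = 1e-6)
  expect_gt(unname(mv["target"]), unname(mv["context"]))
  expect_gt(unname(mv["context"] + mv["interaction"]), 0.01)

  dp <- dpcaFit(tens)
  expect_identical(length(dp@componentMarg), 16L)
  # the top context component aligns with the planted context subspace
  gt <- s@groundTruth
  Lctx <- gt$latentLoading[tens$mask, gt$latentGroups == 3, drop = FALSE]
  Q <- qr.Q(qr(Lctx))
  top <- dp@encoder[, which(dp@componentMarg == "context")[1], drop = FALSE]
  top <- top / sqrt(sum(top^2))
  ang <- acos(min(1, svd(crossprod(Q, top))$d[1])) * 180 / pi
  expect_lt(ang, 15)

  # the effort-shift component tracks active-muscle activation per
  # condition, with opposite signs for flexion and extension groups
  cc <- contextComponentVsMuscle(dp, tens, s)
  expect_gte(abs(cc$correlations[["flexion"]]), 0.9)
  expect_gte(abs(cc$correlations[["extension"]]), 0.9)
  expect_lt(cc$correlations[["flexion"]] * cc$correlations[["extension"]], 0)

  # marginalization variance grows with the planted context shift
  mvSmall <- local({
    cfg <- generatorConfig(seed = 31L, nChannels = 32L,
                           trialsPerBlock = c(25L, 25L),
                           contextShiftScale = 0.5)
    marginalizationVariance(buildTrialTensor(
      generateSession(cfg, c("normal", "spring"), task = "1dof")))
  })
  mvBig <- local({
    cfg <- generatorConfig(seed = 31L, nChannels = 32L,
                           trialsPerBlock = c(25L, 25L),
                           contextShiftScale = 3)
    marginalizationVariance(buildTrialTensor(
      generateSession(cfg, c("normal", "spring"), task = "1dof")))
  })
  expect_gt(unname(mvBig["context"] + mvBig["interaction"]),
            unname(mvSmall["context"] + mvSmall["interaction"]))
})
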