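# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small two-context session: enough trials for binning/tuning/decoding
# tests at a few seconds of build time.
smallSession <- function() fixture("small", function() {
  cfg <- generatorConfig(seed = 11L, nChannels = 32L,
                         trialsPerBlock = c(60L, 60L), fractionFailed = 0.05)
  generateSession(cfg, c("normal", "spring"), task = "1dof")
})

# Multi-context session at the generator's default gains; used by the
# geometry, dPCA, and parameter-recovery tests.
multiCtxSession <- function() fixture("multi", function() {
  cfg <- generatorConfig(seed = 31L, nChannels = 96L,
                         trialsPerBlock = c(60L, 60L), fractionFailed = 0.02)
  generateSession(cfg, c("normal", "spring", "wrist", "band"), task = "1dof")
})

# Independent textbook Kalman step (predict/update written from the
# standard equations, no shared code with the package implementation).
referenceKalmanStep <- function(A, W, C, Q, x, P, y) {
  xp <- A %*% x
  Pp <- A %*% P %*% t(A) + W
  S <- C %*% Pp %*% t(C) + Q
  K <- Pp %*% t(C) %*% solve(S)
  xNew <- drop(xp + K %*% (y - C %*% xp))
  PNew <- (diag(length(x)) - K %*% C) %*% Pp
  list(x = xNew, P = PNew)
}

# Minimum-jerk trace at 1 kHz for closed-form checks.
minJerkPosition <- function(A, Tms, start = 50) {
  tau <- (seq_len(Tms) - 0.5) / Tms
  start + A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}
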