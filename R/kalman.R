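## Position/velocity Kalman filter and ReFIT retraining.
##
## The state is [pos_index, pos_mrs, vel_index, vel_mrs, 1]. Position rows
## of the transition matrix implement physical integration
## (pos' = pos + dt * vel); velocity rows are fit by least squares; the
## constant-1 component is preserved exactly. Online, the virtual finger
## position is updated by integrating the posterior velocity and never by
## the filter's position estimate directly.

.kalmanState <- function(pos = c(50, 50), vel = c(0, 0))
  c(pos, vel, 1)

# Rank-tolerant least squares: pivoted QR, aliased coefficients set to 0
# (a degenerate state component, e.g. identically-zero velocity, then
# simply receives zero weight).
.lsSolve <- function(X, Y) {
  qx <- qr(X)
  cf <- qr.coef(qx, Y)
  cf[is.na(cf)] <- 0
  cf
}

# Slot-wise constructor: a slot named "C" cannot be passed through
# new(Class, ...) because it partially matches the Class argument.
.newKalman <- function(A, W, C, Q, binWidthMs) {
  obj <- new("KalmanDecoder")
  obj@A <- A; obj@W <- W; obj@C <- C; obj@Q <- Q
  obj@binWidthMs <- as.integer(binWidthMs)
  validObject(obj)
  obj
}

#' Fit a position/velocity Kalman filter
#'
#' `A` is fit by least squares on state transitions with the kinematic
#' rows fixed to physical integration; `C` by least squares of features on
#' state; `W` and `Q` from the corresponding residual covariances.
#'
#' @param features bins x channels neural feature matrix (32 ms bins).
#' @param kinematics bins x 4 matrix `[pos_index, pos_mrs, vel_index,
#'   vel_mrs]` on the same grid (percent, percent/s).
#' @param binWidthMs update interval (default 32).
#' @return a [KalmanDecoder-class].
#' @export
fitKalman <- function(features, kinematics, binWidthMs = 32L) {
  stopifnot(nrow(features) == nrow(kinematics), ncol(kinematics) == 4)
  n <- nrow(kinematics)
  if (n <= 5) .stopf("fitKalman: fewer samples than the state dimension")
  dt <- binWidthMs / 1000
  S <- cbind(kinematics, 1)               # n x 5 states
  S0 <- S[-n, , drop = FALSE]
  S1 <- S[-1, , drop = FALSE]

  A <- matrix(0, 5, 5)
  A[1:2, 1:2] <- diag(2)
  A[1:2, 3:4] <- dt * diag(2)
  A[5, 5] <- 1
  # velocity rows by least squares on the full previous state
  Avel <- t(.lsSolve(S0, S1[, 3:4, drop = FALSE]))
  A[3:4, ] <- Avel
  W <- matrix(0, 5, 5)
  residV <- S1[, 3:4, drop = FALSE] - S0 %*% t(Avel)
  W[3:4, 3:4] <- crossprod(residV) / (n - 1)

  Ct <- .lsSolve(S, features)             # 5 x channels
  C <- t(Ct)
  residO <- features - S %*% Ct
  Q <- crossprod(residO) / n
  Q <- (Q + t(Q)) / 2
  .newKalman(A, W, C, Q, binWidthMs)
}

#' One Kalman predict/update step
#'
#' Standard linear-Gaussian recursion on the 5-state; the returned
#' `position` integrates the posterior velocity over one bin and clamps to
#' \[0, 100\]. Non-finite feature vectors reject the update and hold the
#' state.
#'
#' @param decoder a [KalmanDecoder-class].
#' @param state current 5-state (use [kalmanInit()] to start).
#' @param P current 5 x 5 state covariance.
#' @param features observed feature vector for this bin.
#' @return list: `state` (posterior), `P`, `position` (integrated,
#'   clamped).
#' @export
kalmanStep <- function(decoder, state, P, features) {
  A <- decoder@A; W <- decoder@W; C <- decoder@C; Q <- decoder@Q
  dt <- decoder@binWidthMs / 1000
  prevPos <- state[1:2]
  xPred <- drop(A %*% state)
  PPred <- A %*% P %*% t(A) + W
  if (any(!is.finite(features))) {
    pos <- pmin(pmax(prevPos + state[3:4] * dt, 0), 100)
    return(list(state = state, P = P, position = pos, rejected = TRUE))
  }
  Sm <- C %*% PPred %*% t(C) + Q
  K <- t(solve(Sm, C %*% PPred))          # PPred C' Sm^-1
  innov <- features - drop(C %*% xPred)
  xPost <- xPred + drop(K %*% innov)
  PPost <- (diag(5) - K %*% C) %*% PPred
  xPost[5] <- 1
  pos <- pmin(pmax(prevPos + xPost[3:4] * dt, 0), 100)
  xPost[1:2] <- pos
  list(state = xPost, P = PPost, position = pos, rejected = FALSE)
}

#' Initial Kalman state and covariance
#' @param pos starting position (percent).
#' @return list `state`, `P`.
#' @export
kalmanInit <- function(pos = c(50, 50))
  list(state = .kalmanState(pos), P = diag(c(0, 0, 1, 1, 0)))

#' ReFIT retraining of a Kalman decoder
#'
#' Rotates each decoded velocity (magnitude preserved) onto the unit
#' vector from the current position to the target center in the
#' two-dimensional finger space, zeroes the velocity whenever all fingers
#' are inside their targets, and refits the observation matrices `C` and
#' `Q` against the intention-corrected states. `A` and `W` are untouched.
#'
#' @param decoder the [KalmanDecoder-class] used online.
#' @param features bins x channels features recorded online.
#' @param positions bins x 2 decoded positions.
#' @param velocities bins x 2 decoded velocities.
#' @param targets bins x 2 target centers (NA rows are skipped).
#' @param inTarget logical per bin: all fingers inside their targets.
#' @return retrained [KalmanDecoder-class].
#' @export
refitRetrain <- function(decoder, features, positions, velocities,
                         targets, inTarget) {
  keep <- stats::complete.cases(targets)
  if (!any(keep)) .stopf("refitRetrain: no bins carry a target")
  feats <- features[keep, , drop = FALSE]
  pos <- positions[keep, , drop = FALSE]
  vel <- velocities[keep, , drop = FALSE]
  tgt <- targets[keep, , drop = FALSE]
  inT <- inTarget[keep]
  intend <- rotateToTarget(vel, tgt - pos)
  intend[inT, ] <- 0
  S <- cbind(pos, intend, 1)
  Ct <- .lsSolve(S, feats)
  C <- t(Ct)
  residO <- feats - S %*% Ct
  Q <- crossprod(residO) / nrow(feats)
  Q <- (Q + t(Q)) / 2
  .newKalman(decoder@A, decoder@W, C, Q, decoder@binWidthMs)
}

#' Rotate velocities onto target directions, preserving speed
#'
#' @param velocities n x 2 matrix.
#' @param toTarget n x 2 matrix of (target - position) vectors.
#' @return n x 2 matrix of rotated velocities; rows with zero target
#'   distance are returned unchanged.
#' @export
rotateToTarget <- function(velocities, toTarget) {
  speed <- sqrt(rowSums(velocities^2))
  dist <- sqrt(rowSums(toTarget^2))
  unit <- toTarget / ifelse(dist > 0, dist, 1)
  out <- unit * speed
  zero <- dist == 0
  out[zero, ] <- velocities[zero, , drop = FALSE]
  out
}
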