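#' @title Constant-velocity Kalman filter over box state
#'
#' @description
#' The motion state of a tracked object is the 8-vector
#' `(u, v, gamma, h, du, dv, dgamma, dh)`: box centre, aspect ratio, height,
#' and their per-frame velocities. Motion follows a constant-velocity model
#' with a linear observation of the first four components, the standard
#' tracking-by-detection formulation. Process and measurement noise standard
#' deviations scale with the box height `h`, so uncertainty is proportional
#' to apparent object size: position-like terms use `h / 20`, velocity-like
#' terms `h / 160` (the customary weights for this filter family; both are
#' configurable through [tracker_config()]).
#'
#' @param m A measurement: numeric vector `c(u, v, gamma, h)` or a one-row
#'   data frame with those columns.
#' @param state A `kalman_state` as returned by [kf_initiate()].
#' @param std_weight_pos,std_weight_vel Noise scale weights (dimensionless;
#'   multiplied by `h`).
#' @name kalman
NULL

as_meas_vec <- function(m) {
  if (is.data.frame(m)) {
    if (nrow(m) != 1) abort("measurement must be a single row")
    m <- c(m$u, m$v, m$gamma, m$h)
  }
  m <- as.numeric(m)
  if (length(m) != 4 || anyNA(m)) abort("measurement must be numeric (u, v, gamma, h)")
  if (m[3] <= 0 || m[4] <= 0) abort("invalid measurement: gamma and h must be positive")
  m
}

new_kalman_state <- function(mean, cov) {
  structure(list(mean = mean, cov = cov), class = "kalman_state")
}

# transition matrix: position block += velocity block, unit time step
kf_transition <- function() {
  F_ <- diag(8)
  F_[cbind(1:4, 5:8)] <- 1
  F_
}

#' @describeIn kalman Start a filter from a first measurement: zero initial
#'   velocity, diagonal covariance with generous position and velocity
#'   uncertainty scaled by the box height.
#' @return `kf_initiate()`, `kf_predict()`, `kf_update()`: a `kalman_state`
#'   (list with `mean`, an 8-vector, and `cov`, an 8x8 matrix).
#' @export
kf_initiate <- function(m, std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  m <- as_meas_vec(m)
  h <- m[4]
  std <- c(2 * std_weight_pos * h, 2 * std_weight_pos * h, 1e-2,
           2 * std_weight_pos * h,
           10 * std_weight_vel * h, 10 * std_weight_vel * h, 1e-5,
           10 * std_weight_vel * h)
  new_kalman_state(c(m, rep(0, 4)), diag(std^2))
}

#' @describeIn kalman Propagate one frame forward under the
#'   constant-velocity model; covariance grows by the process noise.
#' @export
kf_predict <- function(state, std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  F_ <- kf_transition()
  h <- state$mean[4]
  std <- c(std_weight_pos * h, std_weight_pos * h, 1e-2, std_weight_pos * h,
           std_weight_vel * h, std_weight_vel * h, 1e-5, std_weight_vel * h)
  mean_ <- drop(F_ %*% state$mean)
  cov_ <- F_ %*% state$cov %*% t(F_) + diag(std^2)
  new_kalman_state(mean_, (cov_ + t(cov_)) / 2)
}

# project the state into measurement space: returns mean (4-vec) and
# innovation covariance S = H P H' + R
kf_project <- function(state, std_weight_pos = 1 / 20) {
  h <- state$mean[4]
  std <- c(std_weight_pos * h, std_weight_pos * h, 1e-1, std_weight_pos * h)
  H <- cbind(diag(4), matrix(0, 4, 4))
  S <- H %*% state$cov %*% t(H) + diag(std^2)
  list(mean = state$mean[1:4], S = (S + t(S)) / 2)
}

#' @describeIn kalman Correct a predicted state with a measurement using the
#'   standard Kalman gain; the posterior position variance never exceeds the
#'   prior.
#' @export
kf_update <- function(state, m, std_weight_pos = 1 / 20) {
  m <- as_meas_vec(m)
  proj <- kf_project(state, std_weight_pos)
  H <- cbind(diag(4), matrix(0, 4, 4))
  ch <- tryCatch(chol(proj$S), error = function(e) {
    abort("kalman update failed: innovation covariance not positive definite")
  })
  # gain K = P H' S^{-1} via Cholesky solves
  PHt <- state$cov %*% t(H)
  K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
  innov <- m - proj$mean
  mean_ <- state$mean + drop(K %*% innov)
  cov_ <- (diag(8) - K %*% H) %*% state$cov
  new_kalman_state(mean_, (cov_ + t(cov_)) / 2)
}

#' @describeIn kalman Squared Mahalanobis distance from the predicted
#'   measurement to each candidate measurement, under the innovation
#'   covariance; used for gating association candidates.
#' @param ms A data frame of measurements (columns `u`, `v`, `gamma`, `h`)
#'   or a numeric matrix with 4 columns.
#' @return `kf_gating_distance()`: a non-negative numeric vector, one entry
#'   per measurement.
#' @export
kf_gating_distance <- function(state, ms, std_weight_pos = 1 / 20) {
  if (is.data.frame(ms)) ms <- cbind(ms$u, ms$v, ms$gamma, ms$h)
  ms <- matrix(as.numeric(ms), ncol = 4)
  proj <- kf_project(state, std_weight_pos)
  ch <- tryCatch(chol(proj$S), error = function(e) {
    abort("gating failed: innovation covariance singular")
  })
  d <- sweep(ms, 2, proj$mean)          # n x 4 residuals
  z <- forwardsolve(t(ch), t(d))        # solve L z = d'
  colSums(z^2)
}

#' @export
print.kalman_state <- function(x, ...) {
  cat("<kalman_state>\n")
  cat("  mean:", format(round(x$mean, 3)), "\n")
  cat("  position sd:", format(round(sqrt(diag(x$cov)[1:4]), 3)), "\n")
  invisible(x)
}
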