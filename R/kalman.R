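# Constant-velocity Kalman filter over (cx, cy, w, h) and velocities, the
# 8-state box filter used by modern tracking-by-detection trackers. Process
# and measurement noise are scaled to the box size with standard-deviation
# weight 1/20 for position terms and 1/160 for velocity terms.

KF_STD_POS <- 1 / 20
KF_STD_VEL <- 1 / 160

# box c(x, y, w, h) -> measurement c(cx, cy, w, h)
box_to_meas <- function(box) c(box[[1]] + box[[3]] / 2, box[[2]] + box[[4]] / 2,
                               box[[3]], box[[4]])

meas_to_box <- function(z) bbox(z[1] - z[3] / 2, z[2] - z[4] / 2,
                                max(z[3], 1e-3), max(z[4], 1e-3))

#' Initialise a Kalman track state from a detection box
#'
#' @param box pixel box `c(x, y, w, h)`
#' @return A list of class `kalman_state` with `mean` (8-vector: center,
#'   size, and their per-frame velocities, zero-initialised) and `covariance`
#'   (8 x 8, scaled to the box size).
#' @export
kalman_init <- function(box) {
  z <- box_to_meas(box)
  w <- z[3]; h <- z[4]
  std <- c(2 * KF_STD_POS * w, 2 * KF_STD_POS * h,
           2 * KF_STD_POS * w, 2 * KF_STD_POS * h,
           10 * KF_STD_VEL * w, 10 * KF_STD_VEL * h,
           10 * KF_STD_VEL * w, 10 * KF_STD_VEL * h)
  structure(list(mean = c(z, rep(0, 4)), covariance = diag(std^2)),
            class = "kalman_state")
}

#' Kalman time update (constant-velocity prediction)
#'
#' @param kf a `kalman_state`
#' @return The predicted `kalman_state` one frame ahead.
#' @export
kalman_predict <- function(kf) {
  F8 <- diag(8)
  F8[cbind(1:4, 5:8)] <- 1
  w <- kf$mean[3]; h <- kf$mean[4]
  std <- c(KF_STD_POS * w, KF_STD_POS * h, KF_STD_POS * w, KF_STD_POS * h,
           KF_STD_VEL * w, KF_STD_VEL * h, KF_STD_VEL * w, KF_STD_VEL * h)
  kf$mean <- as.numeric(F8 %*% kf$mean)
  kf$covariance <- F8 %*% kf$covariance %*% t(F8) + diag(std^2)
  kf
}

#' Kalman measurement update
#'
#' @param kf a (predicted) `kalman_state`
#' @param box observed pixel box `c(x, y, w, h)`
#' @return The updated `kalman_state`.
#' @export
kalman_update <- function(kf, box) {
  z <- box_to_meas(box)
  H <- cbind(diag(4), matrix(0, 4, 4))
  w <- kf$mean[3]; h <- kf$mean[4]
  R <- diag(c(KF_STD_POS * w, KF_STD_POS * h,
              KF_STD_POS * w, KF_STD_POS * h)^2)
  S <- H %*% kf$covariance %*% t(H) + R
  K <- kf$covariance %*% t(H) %*% solve(S)
  kf$mean <- as.numeric(kf$mean + K %*% (z - H %*% kf$mean))
  kf$covariance <- (diag(8) - K %*% H) %*% kf$covariance
  kf$covariance <- (kf$covariance + t(kf$covariance)) / 2  # keep symmetric
  kf
}

#' Current box estimate of a Kalman state
#'
#' @param kf a `kalman_state`
#' @return The pixel box `c(x, y, w, h)` projected from the state mean.
#' @export
kalman_box <- function(kf) meas_to_box(kf$mean[1:4])

# Warp a Kalman state through an inter-frame affine camera motion: the 2x2
# linear part acts on every (x, y) pair of the state (center, size,
# velocities); the translation is added to the center only. The covariance
# is propagated through the same linear map.
kalman_warp <- function(kf, motion) {
  if (is_identity_motion(motion)) return(kf)
  M8 <- kronecker(diag(4), motion$A)
  kf$mean <- as.numeric(M8 %*% kf$mean)
  kf$mean[1:2] <- kf$mean[1:2] + motion$t
  kf$mean[3:4] <- abs(kf$mean[3:4])
  kf$covariance <- M8 %*% kf$covariance %*% t(M8)
  kf
}
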