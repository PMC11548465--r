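#' Camera motion as an affine transform
#'
#' Maps previous-frame pixel coordinates to current-frame coordinates:
#' `x' = A x + t`.
#'
#' @param A 2 x 2 linear part
#' @param t length-2 translation
#' @return A list of class `camera_motion`.
#' @export
camera_motion <- function(A = diag(2), t = c(0, 0)) {
  A <- matrix(as.numeric(A), 2L, 2L)
  assert_finite(A, "camera motion")
  assert_finite(t, "camera motion")
  structure(list(A = A, t = as.numeric(t)), class = "camera_motion")
}

is_identity_motion <- function(m) {
  all(m$A == diag(2)) && all(m$t == 0)
}

#' Estimate global camera motion between two frames
#'
#' Detects sparse Harris keypoints in both frames, matches their local patch
#' descriptors (nearest neighbour with ratio and cross-check), and fits an
#' affine transform robustly by random-sample consensus with a final
#' least-squares refit on the inliers. When too few inliers survive, or the
#' fitted transform fails the sanity bound (determinant of the linear part
#' outside `[0.5, 2]`), the identity transform is returned with a warning:
#' coasting uncompensated is safer than warping through a bogus fit.
#'
#' @param prev_frame,curr_frame same-size RGB arrays or grayscale matrices
#' @param max_points keypoints per frame
#' @param inlier_tol inlier residual tolerance in pixels
#' @param iterations random-sample iterations
#' @return A `camera_motion` mapping previous-frame to current-frame
#'   coordinates.
#' @export
estimate_camera_motion <- function(prev_frame, curr_frame, max_points = 150L,
                                   inlier_tol = 2, iterations = 100L,
                                   prev_features = NULL, curr_features = NULL) {
  g1 <- as_gray(prev_frame); g2 <- as_gray(curr_frame)
  if (!identical(dim(g1), dim(g2)))
    stop_validation("frames must have identical dimensions")
  f1 <- prev_features %||% motion_features(g1, max_points)
  f2 <- curr_features %||% motion_features(g2, max_points)
  kp1 <- f1$kp; kp2 <- f2$kp
  fallback <- function(msg) {
    warning("camera motion estimation: ", msg, "; using identity", call. = FALSE)
    camera_motion()
  }
  if (nrow(kp1) < 6L || nrow(kp2) < 6L)
    return(fallback("too few keypoints"))
  mm <- match_descriptors(f1$desc, f2$desc)
  if (nrow(mm) < 6L) return(fallback("too few descriptor matches"))
  P <- kp1[mm[, 1], 1:2, drop = FALSE]
  Q <- kp2[mm[, 2], 1:2, drop = FALSE]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(7L)  # internal, restored: estimation is deterministic in inputs
  n <- nrow(P)
  best_inl <- integer()
  for (it in seq_len(iterations)) {
    s <- sample.int(n, 3L)
    M <- affine_lstsq(P[s, , drop = FALSE], Q[s, , drop = FALSE])
    if (is.null(M)) next
    res <- affine_residuals(M, P, Q)
    inl <- which(res <= inlier_tol)
    if (length(inl) > length(best_inl)) best_inl <- inl
  }
  if (length(best_inl) < 6L) return(fallback("too few inliers"))
  M <- affine_lstsq(P[best_inl, , drop = FALSE], Q[best_inl, , drop = FALSE])
  if (is.null(M)) return(fallback("degenerate inlier set"))
  dt <- det(M$A)
  if (dt < 0.5 || dt > 2) return(fallback("transform outside sanity bounds"))
  M
}

# Sparse keypoints + patch descriptors of a grayscale frame, reusable across
# successive motion estimates.
motion_features <- function(gray, max_points = 150L) {
  kp <- harris_keypoints(gray, max_points = max_points, border = 5L)
  desc <- if (nrow(kp)) {
    t(vapply(seq_len(nrow(kp)),
             function(i) patch_descriptor(gray, kp[i, 1], kp[i, 2]) %||% rep(0, 64),
             numeric(64)))
  } else matrix(numeric(), 0L, 64L)
  list(kp = kp, desc = desc)
}

# Least-squares affine fit Q ~ A P + t; NULL for degenerate configurations.
affine_lstsq <- function(P, Q) {
  X <- cbind(P, 1)
  xt <- tryCatch(qr.solve(X, Q), error = function(e) NULL)
  if (is.null(xt) || !all(is.finite(xt))) return(NULL)
  camera_motion(A = t(xt[1:2, ]), t = xt[3, ])
}

affine_residuals <- function(M, P, Q) {
  pred <- P %*% t(M$A)
  sqrt((pred[, 1] + M$t[1] - Q[, 1])^2 + (pred[, 2] + M$t[2] - Q[, 2])^2)
}

# Apply a camera motion to a box (corners through the affine map).
warp_box <- function(motion, box) {
  if (is_identity_motion(motion)) return(box)
  ctr <- motion$A %*% box_center(box) + motion$t
  sc <- sqrt(abs(det(motion$A)))
  bbox(ctr[1] - box[[3]] * sc / 2, ctr[2] - box[[4]] * sc / 2,
       box[[3]] * sc, box[[4]] * sc)
}
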