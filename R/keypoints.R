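# Sparse keypoints and local appearance descriptors.
#
# The descriptor backend is pluggable by name; the built-in backend "patch"
# is a deterministic Harris-corner detector followed by a mean-centred,
# L2-normalised intensity patch (8 x 8 samples, 64-d). Any local descriptor
# works for the downstream VLAD aggregation; the contract is backend-agnostic.

# Shift a matrix by (di, dj), filling vacated entries with `fill`.
shift_matrix <- function(m, di, dj, fill = -Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ri <- max(1L, 1L - di):min(h, h - di)
  ci <- max(1L, 1L - dj):min(w, w - dj)
  out[ri + di, ci + dj] <- m[ri, ci]
  out
}

# Harris corner detection on a grayscale matrix. Returns an n x 3 matrix
# (x, y, response) in 0-based pixel coordinates, strongest first, with 3x3
# non-maximum suppression and a minimum border margin.
harris_keypoints <- function(gray, max_points = 200L, threshold_rel = 0.002,
                             border = 5L, sigma = 0.8) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 2L * border + 3L || w < 2L * border + 3L) {
    return(matrix(numeric(), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "response"))))
  }
  gx <- (cbind(gray[, -1], gray[, w]) - cbind(gray[, 1], gray[, -w])) / 2
  gy <- (rbind(gray[-1, ], gray[h, ]) - rbind(gray[1, ], gray[-h, ])) / 2
  sxx <- gauss_smooth(gx * gx, sigma)
  syy <- gauss_smooth(gy * gy, sigma)
  sxy <- gauss_smooth(gx * gy, sigma)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  # 3x3 non-maximum suppression via shifted maxima
  nb <- resp
  for (di in -1:1) for (dj in -1:1) {
    if (di || dj) nb <- pmax(nb, shift_matrix(resp, di, dj))
  }
  ok <- resp >= nb & resp > threshold_rel * max(resp, 0)
  ok[c(seq_len(border), h - seq_len(border) + 1L), ] <- FALSE
  ok[, c(seq_len(border), w - seq_len(border) + 1L)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(matrix(numeric(), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "response"))))
  }
  r <- resp[ok]
  ord <- order(-r, idx[, 1], idx[, 2])   # strongest first, deterministic ties
  ord <- ord[seq_len(min(max_points, length(ord)))]
  cbind(x = idx[ord, 2] - 1, y = idx[ord, 1] - 1, response = r[ord])
}

# 8 x 8 mean-centred, L2-normalised intensity patch at a keypoint (0-based
# x, y); returns NULL for flat (zero-variance) patches.
patch_descriptor <- function(gray, x, y) {
  r <- y + 1L; c <- x + 1L
  patch <- gray[(r - 3L):(r + 4L), (c - 3L):(c + 4L)]
  v <- as.numeric(patch) - mean(patch)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-8) return(NULL)
  v / nrm
}

#' Extract local appearance descriptors from an image region
#'
#' Detects sparse keypoints and computes a local descriptor at each. The
#' default (and only built-in) backend, `"patch"`, uses Harris corners with a
#' normalized 8 x 8 intensity-patch descriptor (64-d); it is deterministic
#' given fixed parameters, and textureless regions yield an empty set.
#'
#' @param region RGB (`h x w x 3`) or grayscale (matrix) image with values in
#'   `[0, 1]`; must be at least 16 x 16 pixels
#' @param detector_name descriptor backend name; only `"patch"` is built in
#' @param max_points maximum number of keypoints to keep (strongest first)
#' @return A list of class `descriptor_set` with `descriptors` (n x d matrix)
#'   and `keypoints` (n x 2 matrix of 0-based `(x, y)` positions inside the
#'   region); n may be 0.
#' @export
extract_descriptors <- function(region, detector_name = "patch",
                                max_points = 100L) {
  if (!identical(detector_name, "patch"))
    stop_config("unknown descriptor backend '", detector_name,
                "'; available: \"patch\"")
  gray <- as_gray(region)
  if (nrow(gray) < 16L || ncol(gray) < 16L)
    stop_validation("region must be at least 16 x 16 pixels")
  kp <- harris_keypoints(gray, max_points = max_points, border = 4L)
  descs <- vector("list", nrow(kp))
  keep <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    d <- patch_descriptor(gray, kp[i, 1], kp[i, 2])
    if (!is.null(d)) { descs[[i]] <- d; keep[i] <- TRUE }
  }
  descriptor_set(
    descriptors = if (any(keep)) do.call(rbind, descs[keep]) else matrix(numeric(), 0L, 64L),
    keypoints = kp[keep, 1:2, drop = FALSE]
  )
}

#' Construct a descriptor set
#'
#' @param descriptors n x d numeric matrix, one descriptor per row
#' @param keypoints n x 2 matrix of `(x, y)` pixel positions
#' @return A list of class `descriptor_set`.
#' @export
descriptor_set <- function(descriptors, keypoints) {
  descriptors <- as.matrix(descriptors)
  keypoints <- matrix(as.numeric(keypoints), ncol = 2L)
  if (nrow(descriptors) != nrow(keypoints))
    stop_validation("descriptors and keypoints must have equal length")
  if (nrow(descriptors) > 0L && ncol(descriptors) < 2L)
    stop_validation("descriptor dimension must be at least 2")
  structure(list(descriptors = descriptors, keypoints = keypoints),
            class = "descriptor_set")
}

# Nearest-neighbour descriptor matching with Lowe ratio test and mutual
# cross-check. Returns an m x 2 matrix of row indices (i in a, j in b).
match_descriptors <- function(a, b, ratio = 0.85) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(integer(), ncol = 2L))
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  best_b <- max.col(-d2, ties.method = "first")
  best_a <- max.col(-t(d2), ties.method = "first")
  keep <- logical(na)
  for (i in seq_len(na)) {
    j <- best_b[i]
    if (best_a[j] != i) next
    if (nb > 1L) {
      second <- min(d2[i, -j])
      if (d2[i, j] > ratio^2 * second && second > 1e-12) next
    }
    keep[i] <- TRUE
  }
  cbind(which(keep), best_b[keep])
}
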