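#' Bounding boxes
#'
#' Boxes are length-4 numeric vectors `c(x, y, w, h)` in pixel units:
#' `x`, `y` are the left/top edge, `w`, `h` the width/height. The convention
#' throughout the package is 0-based, half-open: a mask occupying columns
#' 3..6 inclusive has `x = 3`, `w = 4`. Widths and heights must be positive
#' and all coordinates finite.
#'
#' @param x,y left and top edge in pixels
#' @param w,h width and height in pixels, strictly positive
#' @return A named numeric vector `c(x, y, w, h)`.
#' @examples
#' b <- bbox(10, 20, 30, 40)
#' iou(b, b)
#' @export
bbox <- function(x, y, w, h) {
  b <- c(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  if (length(b) < 4L || !all(is.finite(b[1:4])))
    stop_validation("bounding box must have four finite coordinates")
  if (b[[3]] <= 0 || b[[4]] <= 0)
    stop_validation("bounding box width and height must be positive (got w=",
                    b[[3]], ", h=", b[[4]], ")")
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' Area of intersection divided by area of union under the half-open pixel
#' convention. `1 - iou()` is the geometric association cost used by the
#' tracker.
#'
#' @param a,b boxes as `c(x, y, w, h)` (see [bbox()])
#' @return A value in `[0, 1]`; 1 for identical boxes, 0 for disjoint ones.
#' @export
iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  ix <- max(0, min(a[[1]] + a[[3]], b[[1]] + b[[3]]) - max(a[[1]], b[[1]]))
  iy <- max(0, min(a[[2]] + a[[4]], b[[2]] + b[[4]]) - max(a[[2]], b[[2]]))
  inter <- ix * iy
  union <- a[[3]] * a[[4]] + b[[3]] * b[[4]] - inter
  inter / union
}

# Pairwise IoU between two box matrices (n x 4 and m x 4), vectorised over
# the second set; returns an n x m matrix.
iou_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 4L)
  B <- matrix(as.numeric(B), ncol = 4L)
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  areaB <- B[, 3] * B[, 4]
  for (i in seq_len(n)) {
    ix <- pmax(0, pmin(A[i, 1] + A[i, 3], bx2) - pmax(A[i, 1], bx1))
    iy <- pmax(0, pmin(A[i, 2] + A[i, 4], by2) - pmax(A[i, 2], by1))
    inter <- ix * iy
    out[i, ] <- inter / (A[i, 3] * A[i, 4] + areaB - inter)
  }
  out
}

box_center <- function(b) c(b[[1]] + b[[3]] / 2, b[[2]] + b[[4]] / 2)
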