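#' Read a MOTChallenge-style CSV file
#'
#' Parses the plain-text `frame,id,bb_left,bb_top,bb_width,bb_height,conf,...`
#' layout (no header) used for both detection and ground-truth files. Frames
#' and ids are 1-based as stored in the file; pixel coordinates are taken as
#' 0-based box origins (see [bbox()]).
#'
#' @param path path to the file
#' @param kind `"detections"` (id column ignored, `conf` becomes the score) or
#'   `"ground_truth"` (id kept, `conf` treated as a visibility flag and
#'   ignored)
#' @return A data frame. For detections: columns `frame, x, y, w, h, score`.
#'   For ground truth: columns `frame, id, x, y, w, h`. Rows keep file order.
#' @seealso [write_mot()]
#' @export
read_mot <- function(path, kind = c("detections", "ground_truth")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(if (kind == "detections") {
      data.frame(frame = integer(), x = numeric(), y = numeric(),
                 w = numeric(), h = numeric(), score = numeric())
    } else {
      data.frame(frame = integer(), id = integer(), x = numeric(),
                 y = numeric(), w = numeric(), h = numeric())
    })
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop("malformed row (fewer than 6 fields) at line ",
         which(nf < 6L)[1], " of ", path)
  vals <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:min(7L, nf[i])]))
    if (anyNA(v[1:6]))
      stop("non-numeric field at line ", i, " of ", path)
    v
  })
  m <- do.call(rbind, lapply(vals, function(v) c(v[1:6], if (length(v) >= 7L) v[7] else NA_real_)))
  if (any(m[, 5] <= 0 | m[, 6] <= 0)) {
    bad <- which(m[, 5] <= 0 | m[, 6] <= 0)[1]
    stop_validation("non-positive box width/height at line ", bad, " of ", path)
  }
  if (kind == "detections") {
    score <- m[, 7]
    score[is.na(score)] <- 1
    data.frame(frame = as.integer(m[, 1]), x = m[, 3], y = m[, 4],
               w = m[, 5], h = m[, 6], score = score)
  } else {
    df <- data.frame(frame = as.integer(m[, 1]), id = as.integer(m[, 2]),
                     x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6])
    if (anyDuplicated(df[, c("frame", "id")]))
      stop_validation("duplicate (frame, id) pair in ", path)
    df
  }
}

#' Write detections or ground truth in MOTChallenge CSV layout
#'
#' Inverse of [read_mot()]: rows are written as
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,-1,-1,-1`. Detections get
#' `id = -1` and their score in the `conf` column; ground truth gets
#' `conf = 1`.
#'
#' @param df a data frame as returned by [read_mot()]
#' @param path output file path
#' @param kind `"detections"` or `"ground_truth"`
#' @return `path`, invisibly.
#' @export
write_mot <- function(df, path, kind = c("detections", "ground_truth")) {
  kind <- match.arg(kind)
  if (kind == "detections") {
    m <- cbind(df$frame, -1, df$x, df$y, df$w, df$h, df$score, -1, -1, -1)
  } else {
    m <- cbind(df$frame, df$id, df$x, df$y, df$w, df$h, 1, -1, -1, -1)
  }
  lines <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                                 digits = 10), collapse = ","))
  writeLines(if (nrow(df)) lines else character(), path)
  invisible(path)
}

#' Tight bounding box of a binary mask
#'
#' Returns the smallest half-open pixel box containing every foreground
#' (nonzero) pixel of the mask.
#'
#' @param mask a logical or numeric matrix; nonzero entries are foreground.
#'   Row index is y (top = row 1 = y 0), column index is x.
#' @return A box `c(x, y, w, h)`; see [bbox()].
#' @export
mask_to_bbox <- function(mask) {
  if (!is.matrix(mask)) stop_validation("mask must be a matrix")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_validation("mask has no foreground pixels")
  r <- range(idx[, 1]); c <- range(idx[, 2])
  bbox(x = c[1] - 1, y = r[1] - 1, w = c[2] - c[1] + 1, h = r[2] - r[1] + 1)
}

#' Axis-aligned bounding box of a polygon
#'
#' @param vertices an n x 2 matrix (or data frame) of `(x, y)` pixel vertices,
#'   n >= 3
#' @return A box `c(x, y, w, h)` spanning the min/max vertex coordinates.
#' @export
polygon_to_bbox <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop_validation("polygon needs at least 3 vertices")
  if (!all(is.finite(v))) stop_validation("polygon vertices must be finite")
  xr <- range(v[, 1]); yr <- range(v[, 2])
  if (diff(xr) == 0 || diff(yr) == 0)
    stop_validation("degenerate (zero-area) polygon")
  bbox(xr[1], yr[1], diff(xr), diff(yr))
}

#' Convert a pixel box to normalized center format
#'
#' Computes the box center and size relative to the image dimensions, the
#' one-line-per-object text layout used for detector training annotations:
#' `class cx cy nw nh`, all in `[0, 1]`.
#'
#' @param box a pixel box `c(x, y, w, h)`
#' @param image_w,image_h image dimensions in pixels
#' @param class_id integer class label (default 0, the single fruit class)
#' @return A named numeric vector `c(class_id, cx, cy, nw, nh)`.
#' @seealso [denormalize_bbox()] for the exact inverse.
#' @export
normalize_bbox <- function(box, image_w, image_h, class_id = 0L) {
  validate_bbox(box)
  if (box[[1]] < 0 || box[[2]] < 0 ||
      box[[1]] + box[[3]] > image_w || box[[2]] + box[[4]] > image_h)
    stop_validation("box exceeds image bounds")
  c(class_id = as.numeric(class_id),
    cx = (box[[1]] + box[[3]] / 2) / image_w,
    cy = (box[[2]] + box[[4]] / 2) / image_h,
    nw = box[[3]] / image_w,
    nh = box[[4]] / image_h)
}

#' Convert a normalized center-format annotation back to a pixel box
#'
#' @param ann a vector `c(class_id, cx, cy, nw, nh)` as from [normalize_bbox()]
#' @param image_w,image_h image dimensions in pixels
#' @return A pixel box `c(x, y, w, h)`.
#' @export
denormalize_bbox <- function(ann, image_w, image_h) {
  w <- ann[[4]] * image_w
  h <- ann[[5]] * image_h
  bbox(ann[[2]] * image_w - w / 2, ann[[3]] * image_h - h / 2, w, h)
}

#' Write normalized annotations as space-separated text
#'
#' One `class cx cy nw nh` line per object.
#'
#' @param anns a matrix with columns `class_id, cx, cy, nw, nh` (rows may be
#'   vectors from [normalize_bbox()])
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  anns <- matrix(as.numeric(anns), ncol = 5L)
  lines <- apply(anns, 1L, function(r)
    paste(c(format(as.integer(r[1])), format(r[2:5], digits = 10, trim = TRUE)),
          collapse = " "))
  writeLines(if (nrow(anns)) lines else character(), path)
  invisible(path)
}

#' Read normalized annotations written by [write_annotations()]
#'
#' @param path input file path
#' @return A matrix with columns `class_id, cx, cy, nw, nh`, one row per object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- if (length(lines)) {
    do.call(rbind, lapply(strsplit(lines, "[[:space:]]+"), as.numeric))
  } else matrix(numeric(), ncol = 5L)
  colnames(m) <- c("class_id", "cx", "cy", "nw", "nh")
  m
}
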