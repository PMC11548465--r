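#' Scene configuration for the synthetic orchard simulator
#'
#' Describes an orchard-like test video: static, textured, disk-shaped fruit
#' in a speckled background world, a camera panning at constant velocity, and
#' optional opaque vertical occluder strips (stand-ins for branches and
#' posts) fixed in camera coordinates over a frame interval. The defaults
#' produce the desk-scale study scene used throughout the package's test
#' suites: 320 x 240 frames at 30 fps nominal, 120 frames, 25 fruit of 8-14
#' px radius.
#'
#' @param n_apples number of fruit
#' @param frame_size `c(width, height)` in pixels
#' @param n_frames number of frames
#' @param fps nominal frame rate (metadata only)
#' @param camera_velocity `c(vx, vy)` camera pan in px/frame (world fixed,
#'   camera moves; objects shift by `-v` per frame in frame coordinates)
#' @param apple_radius_range `c(min, max)` fruit radius in pixels (> 2)
#' @param occluders list of occluders, each
#'   `list(x = c(x0, x1), frames = c(f0, f1))`: an opaque full-height strip
#'   covering frame-x interval `[x0, x1)` during frames `f0..f1`
#' @param texture_seed RNG seed controlling the entire scene
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_apples = 25L, frame_size = c(320L, 240L),
                         n_frames = 120L, fps = 30L,
                         camera_velocity = c(0, 0),
                         apple_radius_range = c(8, 14),
                         occluders = list(), texture_seed = 1L) {
  if (n_apples < 0L) stop_validation("n_apples must be nonnegative")
  if (any(apple_radius_range <= 2)) stop_validation("fruit radii must exceed 2 px")
  for (oc in occluders) {
    if (oc$x[1] < 0 || oc$x[2] > frame_size[1])
      stop_validation("occluder outside frame bounds")
  }
  structure(list(n_apples = as.integer(n_apples),
                 frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames), fps = as.integer(fps),
                 camera_velocity = as.numeric(camera_velocity),
                 apple_radius_range = as.numeric(apple_radius_range),
                 occluders = occluders, texture_seed = as.integer(texture_seed)),
            class = "scene_config")
}

#' Simulate an orchard video with exact ground truth
#'
#' Renders a seeded world image (speckled background plus shaded, textured
#' fruit disks in two texture families) once, then produces each frame as the
#' camera window crop with occluder strips drawn on top. Ground truth is the
#' visible-region box of each fruit per frame; a fruit more than 80% covered
#' (by occluders or the frame border) is omitted for that frame, and its
#' identity is stable across such gaps. Everything is deterministic given
#' `texture_seed`.
#'
#' @param cfg a [scene_config()]
#' @return A list of class `orchard_scene` with elements
#'   \describe{
#'     \item{frame}{function `f(t)` rendering frame `t` as an `h x w x 3` array}
#'     \item{frames}{function returning a list of all (or selected) frames}
#'     \item{gt}{ground-truth data frame `frame, id, x, y, w, h, vis`}
#'     \item{config}{the resolved configuration}
#'   }
#' @export
simulate_orchard <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
  n <- cfg$n_frames
  offs_x <- round((seq_len(n) - 1L) * cfg$camera_velocity[1])
  offs_y <- round((seq_len(n) - 1L) * cfg$camera_velocity[2])
  w0x <- min(offs_x); w0y <- min(offs_y)
  Ww <- max(offs_x) - w0x + W
  Wh <- max(offs_y) - w0y + H

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$texture_seed)

  # background: green speckle, per-pixel so the camera estimator has texture
  u <- matrix(stats::runif(Wh * Ww), Wh, Ww)
  world <- array(0, c(Wh, Ww, 3L))
  base <- c(0.16, 0.34, 0.12)
  for (ch in 1:3) world[, , ch] <- pmin(1, base[ch] * (0.6 + 0.8 * u))

  # place fruit without overlap (world coordinates, fully inside every frame
  # window vertically/horizontally up to the panned union)
  rmin <- cfg$apple_radius_range[1]; rmax <- cfg$apple_radius_range[2]
  centers <- matrix(numeric(), 0L, 2L)
  radii <- numeric()
  tries <- 0L
  while (length(radii) < cfg$n_apples && tries < 20000L) {
    tries <- tries + 1L
    r <- stats::runif(1, rmin, rmax)
    cx <- stats::runif(1, r + 2, Ww - r - 2)
    cy <- stats::runif(1, r + 2, Wh - r - 2)
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
            r + radii + 2)) {
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
  }
  if (length(radii) < cfg$n_apples)
    stop_validation("could not place ", cfg$n_apples,
                    " non-overlapping fruit; reduce count or radii")
  families <- c(c(0.72, 0.16, 0.10), c(0.70, 0.55, 0.12))
  fam <- rep_len(1:2, length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]; cx <- centers[i, 1]; cy <- centers[i, 2]
    x0 <- floor(cx - r); x1 <- ceiling(cx + r)
    y0 <- floor(cy - r); y1 <- ceiling(cy + r)
    cols <- (x0 + 1L):x1; rows <- (y0 + 1L):y1
    dx <- (cols - 0.5) - cx; dy <- (rows - 0.5) - cy
    d2 <- outer(dy^2, dx^2, "+")
    inside <- d2 <= r^2
    shade <- sqrt(pmax(0, 1 - d2 / r^2))
    # two texture families: fine per-pixel speckle vs coarse 3-px blocks
    if (fam[i] == 1L) {
      tex <- matrix(stats::runif(length(rows) * length(cols)),
                    length(rows), length(cols))
    } else {
      cr <- ceiling(length(rows) / 3); cc <- ceiling(length(cols) / 3)
      coarse <- matrix(stats::runif(cr * cc), cr, cc)
      tex <- coarse[ceiling(seq_along(rows) / 3), ceiling(seq_along(cols) / 3),
                    drop = FALSE]
    }
    col3 <- families[(fam[i] - 1L) * 3L + 1:3]
    lum <- (0.35 + 0.65 * shade) * (0.65 + 0.7 * tex)
    for (ch in 1:3) {
      patch <- world[rows, cols, ch]
      patch[inside] <- pmin(1, col3[ch] * lum[inside])
      world[rows, cols, ch] <- patch
    }
  }

  active_occ <- function(t) {
    Filter(function(oc) t >= oc$frames[1] && t <= oc$frames[2], cfg$occluders)
  }

  frame_fn <- function(t) {
    stopifnot(t >= 1L, t <= n)
    rx <- offs_x[t] - w0x; ry <- offs_y[t] - w0y
    fr <- world[ry + seq_len(H), rx + seq_len(W), , drop = FALSE]
    for (oc in active_occ(t)) {
      cols <- max(1L, floor(oc$x[1]) + 1L):min(W, ceiling(oc$x[2]))
      fr[, cols, ] <- 0.45
    }
    fr
  }

  # ground truth: visible-region boxes in frame coordinates
  gt_rows <- vector("list", n)
  for (t in seq_len(n)) {
    occ <- active_occ(t)
    rows_t <- list()
    for (i in seq_along(radii)) {
      bx <- centers[i, 1] - radii[i] - offs_x[t]
      by <- centers[i, 2] - radii[i] - offs_y[t]
      w <- 2 * radii[i]; h <- w
      vx <- interval_minus(c(max(0, bx), min(W, bx + w)),
                           lapply(occ, function(oc) oc$x))
      vy <- c(max(0, by), min(H, by + h))
      if (is.null(vx) || vy[2] - vy[1] <= 0) next
      frac <- (vx[2] - vx[1]) * (vy[2] - vy[1]) / (w * h)
      if (frac < 0.2) next
      rows_t[[length(rows_t) + 1L]] <- data.frame(
        frame = t, id = i, x = vx[1], y = vy[1],
        w = vx[2] - vx[1], h = vy[2] - vy[1], vis = frac)
    }
    gt_rows[[t]] <- if (length(rows_t)) do.call(rbind, rows_t) else NULL
  }
  gt <- do.call(rbind, gt_rows)
  if (is.null(gt))
    gt <- data.frame(frame = integer(), id = integer(), x = numeric(),
                     y = numeric(), w = numeric(), h = numeric(),
                     vis = numeric())

  structure(list(
    frame = frame_fn,
    frames = function(idx = seq_len(n)) lapply(idx, frame_fn),
    gt = gt, config = cfg,
    centers = centers, radii = radii
  ), class = "orchard_scene")
}

# Largest remaining piece of the interval [iv[1], iv[2]) after removing the
# given [a, b) strips; NULL when nothing (of positive length) remains.
interval_minus <- function(iv, strips) {
  pieces <- list(iv)
  for (s in strips) {
    nxt <- list()
    for (p in pieces) {
      if (s[2] <= p[1] || s[1] >= p[2]) { nxt[[length(nxt) + 1L]] <- p; next }
      if (s[1] > p[1]) nxt[[length(nxt) + 1L]] <- c(p[1], s[1])
      if (s[2] < p[2]) nxt[[length(nxt) + 1L]] <- c(s[2], p[2])
    }
    pieces <- nxt
  }
  if (!length(pieces)) return(NULL)
  lens <- vapply(pieces, function(p) p[2] - p[1], numeric(1))
  if (max(lens) <= 0) return(NULL)
  pieces[[which.max(lens)]]
}

#' Detection corruption configuration
#'
#' Emulates an imperfect detector on top of exact ground truth: independent
#' missed detections, Gaussian corner jitter, Poisson-distributed low-score
#' false positives, and a visibility-dependent confidence model.
#'
#' @param miss_prob probability a ground-truth box is dropped
#' @param jitter_sigma Gaussian corner jitter standard deviation in pixels
#' @param fp_rate expected false positives per frame
#' @param score_model function `f(n, vis)` drawing `n` confidence scores for
#'   boxes of visibility `vis`; the default centres fully visible fruit near
#'   0.9 and degrades steeply with occlusion (a half-occluded fruit scores
#'   near 0.5), the way detector confidence collapses on occluded objects
#' @param seed RNG seed
#' @return A list of class `corruption_config`.
#' @export
corruption_config <- function(miss_prob = 0.05, jitter_sigma = 1,
                              fp_rate = 0.2, score_model = NULL, seed = 1L) {
  if (miss_prob < 0 || miss_prob > 1) stop_validation("miss_prob must be in [0,1]")
  if (jitter_sigma < 0) stop_validation("jitter_sigma must be nonnegative")
  structure(list(miss_prob = miss_prob, jitter_sigma = jitter_sigma,
                 fp_rate = fp_rate,
                 score_model = score_model %||% function(n, vis)
                   pmin(0.99, pmax(0.05, 0.9 - 0.8 * (1 - vis) +
                                     stats::rnorm(n, 0, 0.04))),
                 seed = as.integer(seed)),
            class = "corruption_config")
}

#' Corrupt ground truth into detector-like detections
#'
#' @param gt ground-truth data frame `frame, id, x, y, w, h` (a `vis` column,
#'   if present, feeds the score model; otherwise visibility 1 is assumed)
#' @param cfg a [corruption_config()]
#' @param frame_size `c(width, height)` for placing false positives; inferred
#'   from the ground-truth extent when omitted
#' @return A detections data frame `frame, x, y, w, h, score`, deterministic
#'   given `cfg$seed`.
#' @export
corrupt_detections <- function(gt, cfg = corruption_config(),
                               frame_size = NULL) {
  stopifnot(inherits(cfg, "corruption_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  n <- nrow(gt)
  vis <- if (!is.null(gt$vis)) gt$vis else rep(1, n)
  keep <- if (n) stats::runif(n) >= cfg$miss_prob else logical()
  g <- gt[keep, , drop = FALSE]
  vis <- vis[keep]
  m <- nrow(g)
  if (m) {
    x0 <- g$x + stats::rnorm(m, 0, cfg$jitter_sigma)
    y0 <- g$y + stats::rnorm(m, 0, cfg$jitter_sigma)
    x1 <- g$x + g$w + stats::rnorm(m, 0, cfg$jitter_sigma)
    y1 <- g$y + g$h + stats::rnorm(m, 0, cfg$jitter_sigma)
    det <- data.frame(frame = g$frame, x = pmin(x0, x1 - 1),
                      y = pmin(y0, y1 - 1),
                      w = pmax(1, x1 - x0), h = pmax(1, y1 - y0),
                      score = cfg$score_model(m, vis))
  } else {
    det <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), score = numeric())
  }
  if (cfg$fp_rate > 0 && n) {
    if (is.null(frame_size))
      frame_size <- c(max(gt$x + gt$w), max(gt$y + gt$h))
    fps <- list()
    for (t in seq_len(max(gt$frame))) {
      k <- stats::rpois(1, cfg$fp_rate)
      if (k == 0L) next
      w <- stats::runif(k, 10, 30); h <- stats::runif(k, 10, 30)
      fps[[length(fps) + 1L]] <- data.frame(
        frame = t,
        x = stats::runif(k, 0, max(1, frame_size[1] - w)),
        y = stats::runif(k, 0, max(1, frame_size[2] - h)),
        w = w, h = h, score = stats::runif(k, 0.1, 0.45))
    }
    det <- rbind(det, do.call(rbind, fps))
  }
  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Image and annotation augmentation
#'
#' The augmentation transforms used to expand detector training data:
#' horizontal/vertical flips, brightness/contrast/saturation changes,
#' Gaussian and salt-and-pepper noise, resizing, and horizontal motion blur.
#' Geometric transforms update the normalized annotations consistently
#' (flips reflect the centers; resizing leaves normalized boxes unchanged);
#' photometric transforms leave them untouched. Stochastic transforms are
#' deterministic given `params$seed`.
#'
#' @param image RGB `h x w x 3` array, values in `[0, 1]`
#' @param boxes matrix of normalized annotations, columns
#'   `class_id, cx, cy, nw, nh` (possibly 0 rows)
#' @param op_name one of `"hflip"`, `"vflip"`, `"brightness"`, `"contrast"`,
#'   `"saturation"`, `"gauss_noise"`, `"salt_pepper"`, `"resize"`,
#'   `"motion_blur"`
#' @param params list of op parameters: `delta` (brightness shift),
#'   `factor` (contrast/saturation multiplier), `sd` (Gaussian noise),
#'   `p` (salt-and-pepper fraction), `scale` or `size` (resize),
#'   `length` (blur kernel width), `seed`
#' @return A list with the transformed `image` and `boxes`.
#' @export
augment <- function(image, boxes, op_name, params = list()) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  boxes <- if (length(boxes)) matrix(as.numeric(boxes), ncol = 5L) else
    matrix(numeric(), 0L, 5L)
  clamp <- function(x) pmin(1, pmax(0, x))
  seed <- params$seed %||% 1L
  switch(op_name,
    hflip = {
      image <- image[, dim(image)[2]:1, , drop = FALSE]
      if (nrow(boxes)) boxes[, 2] <- 1 - boxes[, 2]
      list(image = image, boxes = boxes)
    },
    vflip = {
      image <- image[dim(image)[1]:1, , , drop = FALSE]
      if (nrow(boxes)) boxes[, 3] <- 1 - boxes[, 3]
      list(image = image, boxes = boxes)
    },
    brightness = list(image = clamp(image + (params$delta %||% 0.1)), boxes = boxes),
    contrast = list(image = clamp((image - 0.5) * (params$factor %||% 1.2) + 0.5),
                    boxes = boxes),
    saturation = {
      g <- as_gray(image)
      f <- params$factor %||% 1.2
      out <- image
      for (ch in seq_len(dim(image)[3])) out[, , ch] <- clamp(g + f * (image[, , ch] - g))
      list(image = out, boxes = boxes)
    },
    gauss_noise = {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(seed)
      list(image = clamp(image + stats::rnorm(length(image), 0,
                                              params$sd %||% 0.05)),
           boxes = boxes)
    },
    salt_pepper = {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(seed)
      p <- params$p %||% 0.05
      d <- dim(image)
      npix <- d[1] * d[2]
      hit <- stats::runif(npix) < p
      val <- stats::runif(npix) < 0.5
      out <- image
      for (ch in seq_len(d[3])) {
        m <- out[, , ch]
        m[hit] <- as.numeric(val[hit])
        out[, , ch] <- m
      }
      list(image = out, boxes = boxes)
    },
    resize = {
      d <- dim(image)
      if (!is.null(params$size)) {
        nh <- params$size[2]; nw <- params$size[1]
      } else {
        s <- params$scale %||% 0.5
        nh <- max(1L, round(d[1] * s)); nw <- max(1L, round(d[2] * s))
      }
      out <- array(0, c(nh, nw, d[3]))
      for (ch in seq_len(d[3]))
        out[, , ch] <- resize_bilinear(image[, , ch], nh, nw)
      list(image = out, boxes = boxes)   # normalized boxes are scale-free
    },
    motion_blur = {
      L <- params$length %||% 5L
      d <- dim(image)
      out <- array(0, c(d[1], d[2], d[3]))
      offs <- seq_len(L) - (L + 1) / 2
      for (ch in seq_len(d[3])) {
        m <- image[, , ch]
        acc <- matrix(0, d[1], d[2])
        for (o in offs) {
          idx <- pmin(d[2], pmax(1, seq_len(d[2]) + round(o)))
          acc <- acc + m[, idx]
        }
        out[, , ch] <- acc / L
      }
      list(image = out, boxes = boxes)
    },
    stop_config("unknown augmentation op '", op_name, "'")
  )
}

# Bilinear resampling of a single-channel matrix.
resize_bilinear <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  sy <- (seq_len(nh) - 0.5) * h / nh + 0.5
  sx <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(h, pmax(1, floor(sy))); y1 <- pmin(h, y0 + 1)
  x0 <- pmin(w, pmax(1, floor(sx))); x1 <- pmin(w, x0 + 1)
  fy <- pmin(1, pmax(0, sy - y0)); fx <- pmin(1, pmax(0, sx - x0))
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, nh, nw); wx <- matrix(fx, nh, nw, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}
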