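# Shared fixtures: study scenes built in code.

# Static clean scene: 8 fruit, no occluders, static camera.
clean_scene <- function(seed) {
  scene_config(n_apples = 8L, frame_size = c(160L, 120L), n_frames = 40L,
               texture_seed = seed)
}

# Occlusion scene: camera pans right at 2 px/frame past a fixed opaque strip
# wide enough to fully hide any fruit for ~25 frames (under the 30-frame
# track buffer); fruit cross behind it at different times.
occlusion_scene <- function(seed) {
  scene_config(n_apples = 12L, frame_size = c(320L, 240L), n_frames = 120L,
               camera_velocity = c(2, 0),
               occluders = list(list(x = c(145, 175), frames = c(1, 120))),
               texture_seed = seed)
}

# Identity corruption: detections equal ground truth (scores from the model).
identity_corruption <- function(seed = 1L) {
  corruption_config(miss_prob = 0, jitter_sigma = 0, fp_rate = 0, seed = seed)
}

run_occlusion <- function(seed, use_appearance) {
  sc <- simulate_orchard(occlusion_scene(seed))
  det <- corrupt_detections(sc$gt, corruption_config(seed = seed + 100L),
                            frame_size = sc$config$frame_size)
  tr <- track_fruits(det, frames = sc$frame,
                     config = tracker_config(gmc = "sparse",
                                             use_appearance = use_appearance))
  ev <- match_and_tally(sc$gt, tr$results)
  list(count = fruit_count(tr), ids = ev$ids, mota = ev$mota)
}

# Exhaustive-permutation assignment oracle (minimum total cost).
perm_oracle <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# Brute-force single-output convolution (cross-correlation) oracle.
conv_oracle <- function(x, K, stride = 1L, padding = 0L) {
  if (padding > 0L) {
    d <- dim(x)
    xp <- array(0, c(d[1] + 2 * padding, d[2] + 2 * padding, d[3]))
    xp[padding + seq_len(d[1]), padding + seq_len(d[2]), ] <- x
    x <- xp
  }
  k <- dim(K)[1]; cin <- dim(K)[3]; cout <- dim(K)[4]
  ho <- (dim(x)[1] - k) %/% stride + 1L
  wo <- (dim(x)[2] - k) %/% stride + 1L
  out <- array(0, c(ho, wo, cout))
  for (oc in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    s <- 0
    for (ic in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k))
      s <- s + x[(i - 1) * stride + ki, (j - 1) * stride + kj, ic] * K[ki, kj, ic, oc]
    out[i, j, oc] <- s
  }
  out
}

# Brute-force VLAD oracle: exhaustive nearest centroid, residual sums,
# power + L2 normalization.
vlad_oracle <- function(X, C) {
  k <- nrow(C); d <- ncol(C)
  v <- matrix(0, k, d)
  for (i in seq_len(nrow(X))) {
    dist <- apply(C, 1L, function(ce) sum((X[i, ] - ce)^2))
    j <- which.min(dist)
    v[j, ] <- v[j, ] + X[i, ] - C[j, ]
  }
  v <- as.numeric(t(v))
  v <- sign(v) * sqrt(abs(v))
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}
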