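test_that("IoU follows the half-open pixel convention", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)   # grid enumeration
  M <- iou_matrix(rbind(c(0, 0, 2, 2), c(5, 5, 2, 2)),
                  rbind(c(1, 1, 2, 2)))
  expect_equal(M, matrix(c(1 / 7, 0), 2, 1))
})

test_that("gated association matches examples and the permutation oracle", {
  r <- associate(matrix(0.2, 1, 1), gate = 0.5)
  expect_equal(unname(r$matches), matrix(c(1L, 1L), 1))
  r2 <- associate(matrix(0.9, 1, 1), gate = 0.5)
  expect_equal(nrow(r2$matches), 0L)
  expect_equal(r2$unmatched_rows, 1L)
  expect_equal(r2$unmatched_cols, 1L)
  r3 <- associate(matrix(numeric(), 0, 0), gate = 0.5)
  expect_equal(nrow(r3$matches), 0L)

  set.seed(30)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n, n)
    a <- solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), a)]), perm_oracle(C), tolerance = 1e-8)
  }
  # rectangular: min(n, m) pairs, optimal
  C <- rbind(c(10, 1, 10), c(1, 10, 10))
  expect_equal(solve_assignment(C), c(2L, 1L))
  # deterministic tie-break: lowest row, then lowest column
  expect_equal(solve_assignment(matrix(1, 3, 3)), 1:3)
})

test_that("Kalman prediction follows the constant-velocity model and warps", {
  kf <- kalman_init(c(10, 20, 8, 8))
  # stationary track, identity motion: box unchanged
  expect_equal(unname(kalman_box(kalman_predict(kf))), c(10, 20, 8, 8),
               tolerance = 1e-10)
  # velocity (3, 0): center advances by 3 per frame
  kf2 <- kf; kf2$mean[5] <- 3
  b <- kalman_box(kalman_predict(kf2))
  expect_equal(unname(b)[1], 13, tolerance = 1e-10)
  # pure camera translation moves a zero-velocity track by (5, -2)
  mo <- camera_motion(t = c(5, -2))
  b2 <- kalman_box(fruitrack:::kalman_warp(kalman_predict(kf), mo))
  expect_equal(unname(b2), c(15, 18, 8, 8), tolerance = 1e-10)
  # covariance stays symmetric PSD through predict/update
  kf3 <- kalman_update(kalman_predict(kf), c(11, 21, 8, 8))
  expect_equal(kf3$covariance, t(kf3$covariance), tolerance = 1e-10)
  expect_true(all(eigen(kf3$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-9))
})

test_that("track lifecycle: confirmation, loss, and removal", {
  cfg <- tracker_config(gmc = "none", use_appearance = FALSE, track_buffer = 3L)
  trk <- new_tracker(cfg)
  # no detections, no tracks: a no-op
  out0 <- tracker_step(trk, data.frame(x = numeric(), y = numeric(),
                                       w = numeric(), h = numeric(),
                                       score = numeric()), frame_index = 1L)
  expect_equal(nrow(out0), 0L)
  expect_equal(fruit_count(trk), 0L)

  # a confident detection in frames 2 and 3: tentative then confirmed id 1
  d <- data.frame(x = 10, y = 10, w = 20, h = 20, score = 0.9)
  tracker_step(trk, d, frame_index = 2L)
  expect_equal(fruit_count(trk), 0L)            # still tentative
  out <- tracker_step(trk, d, frame_index = 3L)
  expect_equal(fruit_count(trk), 1L)
  expect_equal(out$id, 1L)

  # miss it longer than the buffer: removed
  empty <- d[0, ]
  for (f in 4:7) tracker_step(trk, empty, frame_index = f)
  st <- vapply(trk$tracks, function(t) t$status, character(1))
  expect_true("removed" %in% st)

  # out-of-order frame index is a sequencing error
  expect_error(tracker_step(trk, d, frame_index = 3L), "greater")
})

test_that("tracks on the first processed frame are confirmed immediately", {
  cfg <- tracker_config(gmc = "none", use_appearance = FALSE)
  trk <- new_tracker(cfg)
  d <- data.frame(x = c(10, 50), y = c(10, 50), w = 20, h = 20, score = 0.9)
  out <- tracker_step(trk, d, frame_index = 1L)
  expect_equal(sort(out$id), c(1L, 2L))
  expect_equal(fruit_count(trk), 2L)
})

test_that("assignments are one-to-one and ids sequential without gaps", {
  sc <- simulate_orchard(clean_scene(7L))
  det <- corrupt_detections(sc$gt, corruption_config(seed = 7L),
                            frame_size = sc$config$frame_size)
  tr <- track_fruits(det, config = tracker_config(gmc = "none",
                                                  use_appearance = FALSE))
  res <- tr$results
  for (f in unique(res$frame)) {
    ids <- res$id[res$frame == f]
    expect_equal(anyDuplicated(ids), 0L)
  }
  expect_equal(sort(unique(res$id)), seq_len(tr$count))
})

test_that("counting returns the number of confirmed tracks", {
  cfg <- tracker_config(gmc = "none", use_appearance = FALSE)
  trk <- new_tracker(cfg)
  expect_equal(fruit_count(trk), 0L)
  d <- data.frame(x = 10 * (1:7), y = 10, w = 8, h = 8, score = 0.9)
  tracker_step(trk, d, frame_index = 1L)
  expect_equal(fruit_count(trk), 7L)

  # clean simulated video: count equals the true number of fruit
  sc <- simulate_orchard(scene_config(n_apples = 25L, frame_size = c(320L, 240L),
                                      n_frames = 10L, texture_seed = 5L))
  det <- corrupt_detections(sc$gt, identity_corruption(),
                            frame_size = c(320, 240))
  tr <- track_fruits(det, config = tracker_config(gmc = "none",
                                                  use_appearance = FALSE))
  expect_equal(fruit_count(tr), 25L)
})

test_that("occlusion re-identification needs the appearance rematch", {
  with_app <- run_occlusion(1L, use_appearance = TRUE)
  without <- run_occlusion(1L, use_appearance = FALSE)
  # rematch keeps identities across the occluder; the IoU-only ablation
  # issues new ids for reappearing fruit
  expect_lt(with_app$ids, without$ids)
  expect_lt(with_app$count, without$count)
})
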