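test_that("simulated scenes honour their configuration", {
  # no fruit: background only, empty ground truth
  sc0 <- simulate_orchard(scene_config(n_apples = 0L, frame_size = c(64L, 48L),
                                       n_frames = 3L, texture_seed = 1L))
  expect_equal(nrow(sc0$gt), 0L)
  expect_identical(dim(sc0$frame(1)), c(48L, 64L, 3L))

  # static camera, no occluders: every frame has all fruit with constant ids
  sc <- simulate_orchard(scene_config(n_apples = 5L, frame_size = c(160L, 120L),
                                      n_frames = 6L, texture_seed = 2L))
  for (f in 1:6) {
    g <- sc$gt[sc$gt$frame == f, ]
    expect_equal(nrow(g), 5L)
    expect_equal(sort(g$id), 1:5)
  }
  # boxes inside frame bounds; id set bounded by n_apples
  expect_true(all(sc$gt$x >= 0 & sc$gt$x + sc$gt$w <= 160))
  expect_true(all(sc$gt$y >= 0 & sc$gt$y + sc$gt$h <= 120))
  expect_lte(length(unique(sc$gt$id)), 5L)
})

test_that("camera pan shifts ground truth by minus the pan per frame", {
  sc <- simulate_orchard(scene_config(n_apples = 4L, frame_size = c(200L, 120L),
                                      n_frames = 8L, camera_velocity = c(4, 0),
                                      texture_seed = 3L))
  g <- sc$gt
  for (id in unique(g$id)) {
    tr <- g[g$id == id & g$vis == 1, ]
    if (nrow(tr) < 2) next
    d <- diff(tr$x + tr$w / 2) / diff(tr$frame)
    expect_equal(d, rep(-4, length(d)), tolerance = 1e-9)
  }
  # closed-form: world center minus t * pan
  expect_equal(sc$gt$x[1] + sc$gt$w[1] / 2,
               sc$centers[sc$gt$id[1], 1] - (sc$gt$frame[1] - 1) * 4,
               tolerance = 1e-9)
})

test_that("same seed reproduces frames, ground truth and detections exactly", {
  cfg <- scene_config(n_apples = 6L, frame_size = c(120L, 90L), n_frames = 4L,
                      camera_velocity = c(1, 0), texture_seed = 9L)
  a <- simulate_orchard(cfg); b <- simulate_orchard(cfg)
  expect_identical(a$gt, b$gt)
  expect_identical(a$frame(3), b$frame(3))
  ca <- corrupt_detections(a$gt, corruption_config(seed = 5L),
                           frame_size = c(120, 90))
  cb <- corrupt_detections(b$gt, corruption_config(seed = 5L),
                           frame_size = c(120, 90))
  expect_identical(ca, cb)
})

test_that("detection corruption behaves like the configured detector noise", {
  gt <- do.call(rbind, lapply(1:40, function(f)
    data.frame(frame = f, id = 1:25, x = 10 * (1:25), y = 10, w = 8, h = 8)))
  # identity corruption reproduces the boxes
  d0 <- corrupt_detections(gt, identity_corruption(), frame_size = c(300, 30))
  expect_equal(nrow(d0), nrow(gt))
  expect_equal(d0$x, gt$x)
  expect_true(all(d0$score > 0.5))
  # total miss drops everything
  d1 <- corrupt_detections(gt, corruption_config(miss_prob = 1, fp_rate = 0),
                           frame_size = c(300, 30))
  expect_equal(nrow(d1), 0L)
  # binomial 3-sigma bound on the dropped fraction (1000 boxes, p = 0.2)
  d2 <- corrupt_detections(gt, corruption_config(miss_prob = 0.2,
                                                 jitter_sigma = 0, fp_rate = 0,
                                                 seed = 8L),
                           frame_size = c(300, 30))
  dropped <- 1 - nrow(d2) / nrow(gt)
  expect_gt(dropped, 0.16)
  expect_lt(dropped, 0.24)
})

test_that("augmentations transform images and boxes consistently", {
  set.seed(60)
  img <- array(runif(40 * 30 * 3), c(30, 40, 3))
  boxes <- rbind(c(0, 0.3, 0.4, 0.2, 0.2))

  # horizontal flip reflects centers; applying it twice is the identity
  h1 <- augment(img, boxes, "hflip")
  expect_equal(h1$boxes[1, 2], 0.7)
  h2 <- augment(h1$image, h1$boxes, "hflip")
  expect_equal(h2$image, img)
  expect_equal(h2$boxes, boxes)
  v2 <- augment(augment(img, boxes, "vflip")$image,
                augment(img, boxes, "vflip")$boxes, "vflip")
  expect_equal(v2$image, img)

  # photometric ops keep boxes and stay in range
  for (op in c("brightness", "contrast", "saturation", "gauss_noise",
               "motion_blur")) {
    a <- augment(img, boxes, op, list(seed = 1L))
    expect_equal(a$boxes, boxes)
    expect_true(all(a$image >= 0 & a$image <= 1 + 1e-12))
  }

  # salt-and-pepper corrupts about the requested pixel fraction (3-sigma)
  big <- array(0.5, c(100, 100, 3))
  sp <- augment(big, boxes, "salt_pepper", list(p = 0.1, seed = 2L))
  frac <- mean(sp$image[, , 1] != 0.5)
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.13)

  # resize changes pixels, not normalized boxes
  r <- augment(img, boxes, "resize", list(scale = 0.5))
  expect_identical(dim(r$image)[1:2], c(15L, 20L))
  expect_equal(r$boxes, boxes)

  expect_error(augment(img, boxes, "rotate17"), "unknown")
})

test_that("clean simulation through the tracker gives a perfect evaluation", {
  sc <- simulate_orchard(clean_scene(4L))
  det <- corrupt_detections(sc$gt, identity_corruption(),
                            frame_size = sc$config$frame_size)
  tr <- track_fruits(det, frames = sc$frame,
                     config = tracker_config(gmc = "none"))
  ev <- match_and_tally(sc$gt, tr$results)
  expect_equal(ev$mota, 1)
  expect_equal(ev$ids, 0L)
  expect_equal(fruit_count(tr), 8L)
})
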