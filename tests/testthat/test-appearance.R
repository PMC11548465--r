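test_that("descriptor extraction is deterministic and bounded", {
  # textureless region: no keypoints
  flat <- matrix(0.5, 32, 32)
  ds <- extract_descriptors(flat)
  expect_equal(nrow(ds$descriptors), 0L)

  # checkerboard: at least one keypoint, all inside bounds
  checker <- outer(1:32, 1:32, function(r, c) ((r - 1) %/% 4 + (c - 1) %/% 4) %% 2)
  ds2 <- extract_descriptors(checker)
  expect_gt(nrow(ds2$descriptors), 0L)
  expect_true(all(ds2$keypoints[, 1] >= 0 & ds2$keypoints[, 1] < 32))
  expect_true(all(ds2$keypoints[, 2] >= 0 & ds2$keypoints[, 2] < 32))

  # identical region -> identical descriptor sets
  set.seed(20)
  tex <- matrix(runif(32 * 32), 32, 32)
  expect_identical(extract_descriptors(tex), extract_descriptors(tex))

  expect_error(extract_descriptors(matrix(0.5, 10, 10)), "16 x 16")
  expect_error(extract_descriptors(tex, detector_name = "surf"), "backend")
})

test_that("codebook fitting follows k-means closed forms", {
  set.seed(21)
  X <- matrix(rnorm(50 * 4), 50, 4)
  cb1 <- fit_codebook(X, k = 1L, seed = 3L)
  expect_equal(as.numeric(cb1$centroids), colMeans(X), tolerance = 1e-10)

  # two well-separated blobs: centroids near the blob means
  n <- 200L
  blob1 <- matrix(rnorm(n * 2, mean = 0, sd = 0.5), ncol = 2)
  blob2 <- matrix(rnorm(n * 2, mean = 10, sd = 0.5), ncol = 2)
  cb2 <- fit_codebook(rbind(blob1, blob2), k = 2L, seed = 4L)
  cents <- cb2$centroids[order(cb2$centroids[, 1]), ]
  expect_lt(max(abs(cents[1, ] - colMeans(blob1))), 3 * 0.5 / sqrt(n))
  expect_lt(max(abs(cents[2, ] - colMeans(blob2))), 3 * 0.5 / sqrt(n))

  # identical descriptors, k = 1: centroid is that vector
  same <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  cb3 <- fit_codebook(same, k = 1L, seed = 1L)
  expect_equal(as.numeric(cb3$centroids), c(1, 2, 3))

  expect_error(fit_codebook(X[1:3, ], k = 8L), "at least")
})

test_that("VLAD encoding matches the brute-force oracle", {
  # k = 1, centroid at the origin: residuals are the descriptors themselves
  X <- rbind(c(1, 0), c(0, 2), c(3, 1))
  cb <- structure(list(centroids = matrix(0, 1, 2), k = 1L),
                  class = "vlad_codebook")
  v <- vlad_encode(X, cb)
  raw <- colSums(X)
  expected <- sign(raw) * sqrt(abs(raw))
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(as.numeric(v), expected, tolerance = 1e-12)

  # descriptors exactly on centroids: degenerate all-zero vector
  cb2 <- structure(list(centroids = rbind(c(0, 0), c(5, 5)), k = 2L),
                   class = "vlad_codebook")
  v2 <- vlad_encode(rbind(c(0, 0), c(5, 5)), cb2)
  expect_true(all(v2 == 0))
  expect_true(attr(v2, "degenerate"))

  # random fixture vs exhaustive-loop oracle
  set.seed(22)
  for (i in 1:10) {
    X <- matrix(rnorm(10), 5, 2)
    C <- matrix(rnorm(4), 2, 2)
    cbi <- structure(list(centroids = C, k = 2L), class = "vlad_codebook")
    expect_equal(as.numeric(vlad_encode(X, cbi)), vlad_oracle(X, C),
                 tolerance = 1e-10)
  }

  # empty set -> degenerate
  e <- vlad_encode(matrix(numeric(), 0, 2), cb2)
  expect_true(attr(e, "degenerate"))
  expect_error(vlad_encode(matrix(rnorm(9), 3, 3), cb2), "dimension")
})

test_that("VLAD is permutation-invariant in descriptor order", {
  set.seed(23)
  X <- matrix(rnorm(24), 12, 2)
  C <- matrix(rnorm(8), 4, 2)
  cb <- structure(list(centroids = C, k = 4L), class = "vlad_codebook")
  for (i in 1:5) {
    p <- sample(nrow(X))
    expect_equal(as.numeric(vlad_encode(X[p, ], cb)),
                 as.numeric(vlad_encode(X, cb)), tolerance = 1e-12)
  }
})

test_that("cosine similarity has the right geometry and sentinels", {
  a <- structure(c(1, 0, 0), class = "vlad", degenerate = FALSE)
  b <- structure(c(0, 1, 0), class = "vlad", degenerate = FALSE)
  expect_equal(appearance_similarity(a, a), 1)
  expect_equal(appearance_similarity(a, b), 0)
  expect_equal(appearance_similarity(a, -a), -1)
  # symmetry and scale invariance
  set.seed(24)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(appearance_similarity(x, y), appearance_similarity(y, x))
  expect_equal(appearance_similarity(x, 3.7 * y), appearance_similarity(x, y),
               tolerance = 1e-12)
  # degenerate input yields the no-evidence sentinel, never a number
  dg <- vlad_encode(matrix(numeric(), 0, 2),
                    structure(list(centroids = matrix(0, 1, 2), k = 1L),
                              class = "vlad_codebook"))
  expect_true(is.na(appearance_similarity(dg, dg)))
  expect_true(is.na(appearance_similarity(x[1:2], as.numeric(dg))))
  expect_error(appearance_similarity(x, y[1:3]), "dimension")
})

test_that("displacement validation accepts consistent motion (closed boundary)", {
  cand <- list(track = c(0, 0), detection = c(5, 0))
  anch <- list(track = c(10, 10), detection = c(15, 10))
  expect_true(validate_match(cand, anch, tolerance = 3))
  # opposite displacement: difference 10 > 3
  anch2 <- list(track = c(10, 10), detection = c(5, 10))
  expect_false(validate_match(cand, anch2, tolerance = 3))
  # boundary: difference exactly equal to tolerance is accepted
  anch3 <- list(track = c(0, 0), detection = c(2, 0))
  expect_true(validate_match(cand, anch3, tolerance = 3))
  # no anchor: vacuously true
  expect_true(validate_match(cand, NULL, tolerance = 0))
})

test_that("same-fruit crops are more similar than different-fruit crops", {
  sc <- simulate_orchard(scene_config(n_apples = 6L, frame_size = c(200L, 150L),
                                      n_frames = 2L, texture_seed = 42L))
  f1 <- sc$frame(1)
  gt1 <- sc$gt[sc$gt$frame == 1, ]
  crop_at <- function(row, dx = 0, dy = 0) {
    g <- gt1[row, ]
    fruitrack:::crop_region(f1, c(g$x + dx, g$y + dy, g$w, g$h), 0.1)
  }
  pool <- do.call(rbind, lapply(seq_len(nrow(gt1)), function(r)
    extract_descriptors(crop_at(r))$descriptors))
  cb <- fit_codebook(pool, k = 8L, seed = 1L)
  sig <- function(r, dx = 0, dy = 0)
    vlad_encode(extract_descriptors(crop_at(r, dx, dy)), cb)

  set.seed(42)
  wins <- 0L; trials <- 100L
  for (i in seq_len(trials)) {
    r <- sample(nrow(gt1), 2L)            # two different fruit
    dx <- sample(-2:2, 1); dy <- sample(-2:2, 1)
    s_same <- appearance_similarity(sig(r[1]), sig(r[1], dx, dy))
    s_diff <- appearance_similarity(sig(r[1]), sig(r[2], dx, dy))
    if (!is.na(s_same) && !is.na(s_diff) && s_same > s_diff) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
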