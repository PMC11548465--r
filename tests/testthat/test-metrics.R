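test_that("precision and recall are exact ratios with 0/0 sentinels", {
  expect_equal(unname(precision_recall(10, 0, 0)), c(1, 1))
  expect_equal(unname(precision_recall(5, 5, 15)), c(0.5, 0.25))
  expect_true(is.na(precision_recall(0, 0, 3)[["precision"]]))
  expect_equal(precision_recall(0, 0, 3)[["recall"]], 0)
  expect_error(precision_recall(-1, 0, 0), "nonnegative")
})

test_that("average precision integrates the precision envelope", {
  expect_equal(average_precision(structure(TRUE, n_gt = 1)), 1)
  expect_equal(average_precision(structure(c(FALSE, FALSE), n_gt = 3)), 0)
  # hand-enumerated PR points for [TP, FP, TP] with 2 ground truths:
  # recalls .5 .5 1, precisions 1 .5 2/3; envelope 1 2/3 2/3
  # AP = 0.5 * 1 + 0.5 * 2/3
  expect_equal(average_precision(structure(c(TRUE, FALSE, TRUE), n_gt = 2)),
               0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  # flipping a TP to FP never increases AP
  set.seed(50)
  for (i in 1:10) {
    lab <- runif(12) > 0.4
    ap <- average_precision(structure(lab, n_gt = 8))
    j <- which(lab)[1]
    if (is.na(j)) next
    lab2 <- lab; lab2[j] <- FALSE
    expect_lte(average_precision(structure(lab2, n_gt = 8)), ap + 1e-12)
  }
})

test_that("detection labelling matches greedily by score at IoU 0.5", {
  gt <- data.frame(frame = c(1L, 1L), id = 1:2,
                   x = c(0, 50), y = c(0, 50), w = 10, h = 10)
  det <- data.frame(frame = 1L,
                    x = c(1, 49, 80), y = c(1, 49, 80),
                    w = 10, h = 10, score = c(0.9, 0.8, 0.7))
  lab <- label_detections(det, gt)
  expect_equal(as.logical(lab), c(TRUE, TRUE, FALSE))
  expect_equal(attr(lab, "n_gt"), 2L)
  # each ground truth claimed once: a duplicate detection is a false positive
  det2 <- rbind(det[1, ], det[1, ])
  det2$score <- c(0.9, 0.85)
  expect_equal(as.logical(label_detections(det2, gt)), c(TRUE, FALSE))
})

test_that("mean AP is the arithmetic mean", {
  expect_equal(mean_ap(1), 1)
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  set.seed(51)
  v <- runif(5)
  expect_equal(mean_ap(v), sum(v) / 5)
})

test_that("MOTA follows its formula, including negative values", {
  t1 <- data.frame(frame = 1L, m = 0L, fp = 0L, mme = 0L, g = 5L)
  expect_equal(mota(t1), 1)
  t2 <- data.frame(frame = 1L, m = 1L, fp = 1L, mme = 0L, g = 10L)
  expect_equal(mota(t2), 0.8)
  # multi-frame fixture vs scalar summation oracle
  set.seed(52)
  tt <- data.frame(frame = 1:20, m = rpois(20, 1), fp = rpois(20, 1),
                   mme = rpois(20, 0.3), g = 5L + rpois(20, 3))
  tt$m <- pmin(tt$m, tt$g)
  expect_equal(mota(tt), 1 - sum(tt$m + tt$fp + tt$mme) / sum(tt$g))
  # can be negative; errors on zero ground truth
  t3 <- data.frame(frame = 1L, m = 2L, fp = 9L, mme = 0L, g = 2L)
  expect_lt(mota(t3), 0)
  expect_error(mota(data.frame(frame = 1L, m = 0L, fp = 0L, mme = 0L, g = 0L)),
               "positive")
})

test_that("frame matching: perfect results give MOTA 1 and a flip gives IDS 1", {
  gt <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, id = 1:3, x = c(0, 30, 60) + f, y = 10, w = 8, h = 8)))
  ev <- match_and_tally(gt, gt)
  expect_equal(ev$mota, 1)
  expect_equal(ev$ids, 0L)
  expect_equal(sum(ev$tally$m), 0L)
  expect_equal(sum(ev$tally$fp), 0L)

  # one identity flips at frame 6
  res <- gt
  res$id[res$frame >= 6 & res$id == 2] <- 9L
  ev2 <- match_and_tally(gt, res)
  expect_equal(ev2$ids, 1L)
  expect_equal(sum(ev2$tally$m), 0L)
})

test_that("frame matching agrees with a naive per-frame oracle", {
  set.seed(53)
  gt <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, id = 1:4,
               x = c(0, 25, 50, 75), y = 10 + f, w = 10, h = 10)))
  res <- gt
  res$x <- res$x + rnorm(nrow(res), 0, 1.5)
  drop <- sample(nrow(res), 5)
  res <- res[-drop, ]
  ev <- match_and_tally(gt, res)

  # oracle: quadratic loop, same persistence + gating rules
  last <- list(); prev_pair <- list()
  m <- fp <- mme <- 0L
  for (f in 1:8) {
    G <- gt[gt$frame == f, ]; R <- res[res$frame == f, ]
    taken <- rep(FALSE, nrow(R)); gm <- rep(NA_integer_, nrow(G))
    for (gi in seq_len(nrow(G))) {
      pid <- prev_pair[[as.character(G$id[gi])]]
      if (!is.null(pid)) {
        ri <- match(pid, R$id)
        if (!is.na(ri) && !taken[ri] &&
            iou(as.numeric(G[gi, c("x", "y", "w", "h")]),
                as.numeric(R[ri, c("x", "y", "w", "h")])) >= 0.5) {
          gm[gi] <- ri; taken[ri] <- TRUE
        }
      }
    }
    repeat {
      best <- c(NA, NA); bc <- 0.5 - 1e-12
      for (gi in which(is.na(gm))) for (ri in which(!taken)) {
        v <- iou(as.numeric(G[gi, c("x", "y", "w", "h")]),
                 as.numeric(R[ri, c("x", "y", "w", "h")]))
        if (v > bc) { bc <- v; best <- c(gi, ri) }
      }
      if (is.na(best[1])) break
      gm[best[1]] <- best[2]; taken[best[2]] <- TRUE
    }
    prev_pair <- list()
    for (gi in seq_len(nrow(G))) {
      if (is.na(gm[gi])) { m <- m + 1L; next }
      gid <- as.character(G$id[gi]); rid <- R$id[gm[gi]]
      if (!is.null(last[[gid]]) && last[[gid]] != rid) mme <- mme + 1L
      last[[gid]] <- rid; prev_pair[[gid]] <- rid
    }
    fp <- fp + nrow(R) - sum(taken)
  }
  expect_equal(sum(ev$tally$m), m)
  expect_equal(sum(ev$tally$fp), fp)
  expect_equal(ev$ids, mme)
})

test_that("counting error is the mean relative absolute error", {
  expect_equal(mae(c(10, 20), c(10, 20)), 0)
  expect_equal(mae(c(11, 9), c(10, 10)), 0.1)
  set.seed(54)
  y <- rpois(7, 50); g <- rpois(7, 50) + 1L
  expect_equal(mae(y, g), mean(abs(y - g) / g))
  # invariant under common scaling
  expect_equal(mae(3 * y, 3 * g), mae(y, g))
  expect_error(mae(c(1, 2), c(1, 0)), "positive")
  expect_error(mae(numeric(), numeric()), "nonempty")
})

test_that("count-vs-truth fit matches the closed-form normal equations", {
  gt <- c(10, 20, 30, 40)
  expect_equal(unname(linear_fit_r2(gt, 2 * gt + 1)), c(2, 1, 1),
               tolerance = 1e-12)
  expect_equal(linear_fit_r2(gt, rep(5, 4))[["r2"]], 0)
  set.seed(55)
  x <- runif(9, 10, 100); y <- 1.1 * x + rnorm(9, 0, 3)
  fit <- linear_fit_r2(x, y)
  # closed-form slope/intercept/R^2
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(unname(fit), c(b, a, r2), tolerance = 1e-10)
  expect_error(linear_fit_r2(rep(3, 4), 1:4), "distinct")
})
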