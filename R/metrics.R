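#' Precision and recall from detection counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. Values are returned as
#' fractions in `[0, 1]`; format as percentages only at the reporting layer.
#' An undefined ratio (0/0) yields `NA`.
#'
#' @param tp,fp,fn nonnegative counts of true positives, false positives and
#'   false negatives
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop_validation("counts must be nonnegative")
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Label ranked detections against ground truth
#'
#' Greedy matching for the precision-recall curve: detections are taken in
#' descending score order and matched to the highest-IoU still-unmatched
#' ground-truth box of the same frame at `IoU >= iou_thresh`; each
#' ground-truth box can be claimed once.
#'
#' @param detections data frame `frame, x, y, w, h, score`
#' @param gt data frame `frame, id, x, y, w, h`
#' @param iou_thresh IoU threshold (default 0.5)
#' @return Logical vector of TP labels, in descending-score order, with the
#'   number of ground-truth boxes as attribute `n_gt`.
#' @export
label_detections <- function(detections, gt, iou_thresh = 0.5) {
  ord <- order(-detections$score, detections$frame)
  det <- detections[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(gt$frame == det$frame[i] & !used)
    if (!length(cand)) next
    ious <- iou_matrix(matrix(as.numeric(det[i, c("x", "y", "w", "h")]), 1L),
                       as.matrix(gt[cand, c("x", "y", "w", "h")]))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  structure(tp, n_gt = nrow(gt))
}

#' Average precision (area under the precision-recall curve)
#'
#' All-point interpolation: precision is replaced by its running maximum from
#' the right (the envelope) and integrated as a step function over recall.
#'
#' @param tp_labels logical vector of TP/FP labels in descending score order
#'   (e.g. from [label_detections()])
#' @param n_gt number of ground-truth objects (>= 1); defaults to the
#'   `n_gt` attribute of `tp_labels`
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp_labels, n_gt = attr(tp_labels, "n_gt")) {
  if (is.null(n_gt) || n_gt < 1) stop_validation("n_gt must be >= 1")
  if (!length(tp_labels) || !any(tp_labels)) return(0)
  tp <- cumsum(tp_labels)
  fp <- cumsum(!tp_labels)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  env <- rev(cummax(rev(precision)))     # precision envelope
  dr <- diff(c(0, recall))
  sum(dr * env)
}

#' Mean average precision over classes
#'
#' @param per_class_ap numeric vector of per-class AP values
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(per_class_ap) {
  if (!length(per_class_ap)) stop_validation("need at least one class")
  mean(per_class_ap)
}

#' Multiple-object tracking accuracy
#'
#' `MOTA = 1 - sum(m_t + fp_t + mme_t) / sum(g_t)` over frames, where `m_t`
#' are misses, `fp_t` false positives, `mme_t` identity switches and `g_t`
#' the ground-truth object count. May be negative; equals 1 iff all error
#' counts are zero.
#'
#' @param tally data frame with per-frame columns `m, fp, mme, g` (as from
#'   [match_and_tally()]), or a list containing such a `tally`
#' @return MOTA as a fraction `<= 1`.
#' @export
mota <- function(tally) {
  if (is.list(tally) && !is.data.frame(tally) && !is.null(tally$tally))
    tally <- tally$tally
  if (any(tally$m > tally$g)) stop_validation("misses cannot exceed ground truth")
  G <- sum(tally$g)
  if (G <= 0) stop_validation("total ground-truth count must be positive")
  1 - sum(tally$m + tally$fp + tally$mme) / G
}

#' Frame-by-frame matching of tracker output against ground truth
#'
#' CLEAR-MOT style evaluation: per frame, ground-truth boxes are matched to
#' result boxes by IoU-gated minimum-cost assignment, with match persistence
#' (a ground-truth identity keeps its previous result id when that pairing is
#' still above the gate). An identity switch (`mme`) is counted when a
#' ground-truth identity's matched result id differs from the id at its most
#' recent previously matched frame.
#'
#' @param gt ground-truth data frame `frame, id, x, y, w, h`
#' @param results tracker output data frame `frame, id, x, y, w, h`
#' @param iou_thresh matching gate (default 0.5)
#' @return A list with `tally` (per-frame data frame `frame, m, fp, mme, g`),
#'   `ids` (total identity switches), and `mota`.
#' @export
match_and_tally <- function(gt, results, iou_thresh = 0.5) {
  frames <- sort(unique(c(gt$frame, results$frame)))
  last_id <- integer(0)      # names: gt id -> last matched result id
  pair_of <- integer(0)      # names: gt id -> result id matched in prev frame
  tally <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    G <- gt[gt$frame == f, , drop = FALSE]
    R <- results[results$frame == f, , drop = FALSE]
    ng <- nrow(G); nr <- nrow(R)
    gmatch <- rep(NA_integer_, ng)   # index into R
    if (ng && nr) {
      M <- iou_matrix(as.matrix(G[, c("x", "y", "w", "h")]),
                      as.matrix(R[, c("x", "y", "w", "h")]))
      # persistence: keep previous pairings still above the gate
      taken_r <- logical(nr)
      for (gi in seq_len(ng)) {
        pid <- pair_of[as.character(G$id[gi])]
        if (length(pid) == 1L && !is.na(pid)) {
          ri <- match(pid, R$id)
          if (!is.na(ri) && !taken_r[ri] && M[gi, ri] >= iou_thresh) {
            gmatch[gi] <- ri
            taken_r[ri] <- TRUE
          }
        }
      }
      gleft <- which(is.na(gmatch)); rleft <- which(!taken_r)
      if (length(gleft) && length(rleft)) {
        res <- associate(1 - M[gleft, rleft, drop = FALSE],
                         gate = 1 - iou_thresh)
        if (nrow(res$matches))
          gmatch[gleft[res$matches[, 1]]] <- rleft[res$matches[, 2]]
      }
    }
    mme <- 0L
    new_pair <- integer(0)
    for (gi in which(!is.na(gmatch))) {
      gid <- as.character(G$id[gi])
      rid <- R$id[gmatch[gi]]
      prev <- last_id[gid]
      if (length(prev) == 1L && !is.na(prev) && prev != rid) mme <- mme + 1L
      last_id[gid] <- rid
      new_pair[gid] <- rid
    }
    pair_of <- new_pair
    tally[[fi]] <- data.frame(frame = f, m = sum(is.na(gmatch)),
                              fp = nr - sum(!is.na(gmatch)), mme = mme, g = ng)
  }
  tally <- if (length(tally)) do.call(rbind, tally) else
    data.frame(frame = integer(), m = integer(), fp = integer(),
               mme = integer(), g = integer())
  list(tally = tally, ids = sum(tally$mme), mota = mota(tally))
}

#' Mean relative counting error over videos
#'
#' `MAE = (1/m) * sum(|y_i - gt_i| / gt_i)`: the per-video relative absolute
#' counting error, averaged over videos.
#'
#' @param y predicted per-video counts
#' @param gt true per-video counts, all positive
#' @return MAE, `>= 0`.
#' @export
mae <- function(y, gt) {
  if (length(y) != length(gt) || !length(y))
    stop_validation("y and gt must be nonempty and of equal length")
  if (any(gt <= 0)) stop_validation("all true counts must be positive")
  mean(abs(y - gt) / gt)
}

#' Linear fit of predicted counts against ground truth
#'
#' Ordinary least squares of the predicted count on the true count, with the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` (defined as 0
#' when the response is constant).
#'
#' @param gt true per-video counts (>= 2 distinct values)
#' @param y predicted per-video counts
#' @return Named vector `c(slope, intercept, r2)`.
#' @export
linear_fit_r2 <- function(gt, y) {
  if (length(unique(gt)) < 2L)
    stop_validation("need at least two distinct true counts")
  fit <- stats::lm(y ~ gt)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  c(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
    r2 = r2)
}
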