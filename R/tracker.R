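#' Tracker configuration
#'
#' Thresholds governing association and track lifecycle. The defaults are the
#' published operating point of the tracker: detections are split at
#' `track_high_thresh`/`track_low_thresh` into the two association stages,
#' IoU matches are gated at `match_thresh` on the cost `1 - IoU`, appearance
#' rematches are gated at `appearance_thresh` on cosine distance, new tracks
#' require `new_track_thresh` confidence, and lost tracks survive
#' `track_buffer` frames.
#'
#' @param track_high_thresh confidence split for first-stage detections (0.5)
#' @param track_low_thresh minimum confidence considered at all (0.1)
#' @param new_track_thresh minimum confidence to open a new track (0.7)
#' @param match_thresh IoU-cost gate, `1 - IoU <= match_thresh` (0.5)
#' @param track_buffer frames a lost track is retained (30)
#' @param appearance_thresh cosine-distance gate for appearance rematch (0.5)
#' @param use_appearance enable the VLAD rematch stages (`TRUE`); with
#'   `FALSE` the tracker reduces to the IoU-only two-stage baseline
#' @param gmc camera-motion compensation: `"sparse"` (keypoint-based affine
#'   estimation from the frames) or `"none"`
#' @param codebook_k VLAD codebook size (8)
#' @param codebook_seed seed for the codebook k-means (1)
#' @param displacement_tol displacement-consistency tolerance in pixels at a
#'   reference frame width of 1920; scaled proportionally to the actual frame
#'   width with a 5 px floor (detector jitter is absolute, not relative)
#' @param crop_pad fractional padding around the detection box for descriptor
#'   extraction (0.1)
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(track_high_thresh = 0.5,
                           track_low_thresh = 0.1,
                           new_track_thresh = 0.7,
                           match_thresh = 0.5,
                           track_buffer = 30L,
                           appearance_thresh = 0.5,
                           use_appearance = TRUE,
                           gmc = c("sparse", "none"),
                           codebook_k = 8L,
                           codebook_seed = 1L,
                           displacement_tol = 10,
                           crop_pad = 0.1) {
  gmc <- match.arg(gmc)
  if (!(track_low_thresh >= 0 && track_low_thresh < track_high_thresh &&
        track_high_thresh <= 1))
    stop_validation("need 0 <= track_low_thresh < track_high_thresh <= 1")
  if (new_track_thresh < track_high_thresh)
    stop_validation("new_track_thresh must be >= track_high_thresh")
  if (track_buffer < 1L) stop_validation("track_buffer must be >= 1")
  structure(list(track_high_thresh = track_high_thresh,
                 track_low_thresh = track_low_thresh,
                 new_track_thresh = new_track_thresh,
                 match_thresh = match_thresh,
                 track_buffer = as.integer(track_buffer),
                 appearance_thresh = appearance_thresh,
                 use_appearance = isTRUE(use_appearance),
                 gmc = gmc,
                 codebook_k = as.integer(codebook_k),
                 codebook_seed = as.integer(codebook_seed),
                 displacement_tol = displacement_tol,
                 crop_pad = crop_pad),
            class = "tracker_config")
}

#' Create an empty online tracker
#'
#' @param config a [tracker_config()]
#' @return An environment of class `fruit_tracker` holding the track ledger;
#'   advance it one frame at a time with [tracker_step()].
#' @export
new_tracker <- function(config = tracker_config()) {
  trk <- new.env(parent = emptyenv())
  trk$config <- config
  trk$tracks <- list()
  trk$next_id <- 1L
  trk$frame_index <- 0L
  trk$codebook <- NULL
  trk$desc_pool <- NULL
  trk$prev_frame <- NULL
  trk$stats <- c(rematch_tried = 0L, rematch_gated = 0L, rematch_accepted = 0L)
  class(trk) <- "fruit_tracker"
  trk
}

# Pixel crop of a box padded by `pad` (fraction of box size), clipped to the
# frame and grown to at least 16 x 16 where possible; NULL if the frame is
# too small.
crop_region <- function(frame, box, pad = 0.1) {
  g <- as_gray(frame)
  h <- nrow(g); w <- ncol(g)
  px <- box[[3]] * pad; py <- box[[4]] * pad
  x0 <- floor(box[[1]] - px); x1 <- ceiling(box[[1]] + box[[3]] + px)
  y0 <- floor(box[[2]] - py); y1 <- ceiling(box[[2]] + box[[4]] + py)
  # grow to the minimum descriptor region
  while (x1 - x0 < 16L) { x0 <- x0 - 1L; x1 <- x1 + 1L }
  while (y1 - y0 < 16L) { y0 <- y0 - 1L; y1 <- y1 + 1L }
  x0 <- max(0L, x0); y0 <- max(0L, y0)
  x1 <- min(w, x1); y1 <- min(h, y1)
  if (x1 - x0 < 16L || y1 - y0 < 16L) return(NULL)
  g[(y0 + 1L):y1, (x0 + 1L):x1]
}

# Appearance signature of a detection crop; pools descriptors until the
# codebook can be fitted, then encodes. Returns a vlad vector (possibly
# degenerate) or NULL while no codebook exists.
.signature <- function(trk, frame, box) {
  crop <- crop_region(frame, box, pad = trk$config$crop_pad)
  if (is.null(crop)) return(vlad_degenerate(1L))
  ds <- extract_descriptors(crop)
  if (is.null(trk$codebook)) {
    if (nrow(ds$descriptors) > 0L)
      trk$desc_pool <- rbind(trk$desc_pool, ds$descriptors)
    pool_target <- 8L * trk$config$codebook_k
    if (!is.null(trk$desc_pool) && nrow(unique(trk$desc_pool)) >= pool_target) {
      trk$codebook <- fit_codebook(trk$desc_pool, k = trk$config$codebook_k,
                                   seed = trk$config$codebook_seed)
      trk$desc_pool <- NULL
    } else {
      return(NULL)
    }
  }
  vlad_encode(ds, trk$codebook)
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame pipeline: camera-motion-compensated Kalman
#' prediction; confidence split of the detections; first-stage IoU
#' association of high-confidence detections; appearance (VLAD) rematch of
#' the first-stage leftovers under the displacement-consistency validation;
#' second-stage IoU association of low-confidence detections; appearance
#' rematch of the second-stage leftovers; then measurement updates, track
#' lifecycle transitions, and creation of tentative tracks (confirmed, and
#' assigned the next sequential id, on their second consecutive match).
#'
#' @param trk a `fruit_tracker` from [new_tracker()]
#' @param detections data frame with columns `x, y, w, h, score` for this
#'   frame (extra columns ignored)
#' @param frame optional RGB array or grayscale matrix of the current frame;
#'   required for camera-motion compensation and appearance rematching
#' @param frame_index strictly increasing integer frame number; defaults to
#'   the previous index + 1, or to `detections$frame` when present
#' @return Invisibly, a data frame of this frame's confirmed-track outputs
#'   (`frame, id, x, y, w, h, score`).
#' @export
tracker_step <- function(trk, detections, frame = NULL, frame_index = NULL) {
  cfg <- trk$config
  if (is.null(frame_index)) {
    frame_index <- if (!is.null(detections$frame) && nrow(detections) > 0L)
      unique(detections$frame) else trk$frame_index + 1L
  }
  if (length(frame_index) != 1L || frame_index <= trk$frame_index)
    stop("frame index must be a single value greater than ", trk$frame_index,
         " (got ", paste(frame_index, collapse = ","), ")")
  frame_index <- as.integer(frame_index)
  first_step <- trk$frame_index == 0L

  # (1) camera motion + Kalman prediction (grayscale computed once per frame;
  # previous-frame keypoints/descriptors cached across steps)
  gframe <- if (!is.null(frame)) as_gray(frame)
  motion <- camera_motion()
  if (cfg$gmc == "sparse" && !is.null(gframe) && !is.null(trk$prev_frame)) {
    feat <- motion_features(gframe)
    motion <- estimate_camera_motion(trk$prev_frame, gframe,
                                     prev_features = trk$prev_feat,
                                     curr_features = feat)
    trk$prev_feat <- feat
  } else if (cfg$gmc == "sparse" && !is.null(gframe)) {
    trk$prev_feat <- motion_features(gframe)
  }
  live <- which(vapply(trk$tracks, function(t) t$status != "removed", logical(1)))
  for (i in live) {
    t <- trk$tracks[[i]]
    t$kf <- kalman_warp(kalman_predict(t$kf), motion)
    t$pred_box <- kalman_box(t$kf)
    trk$tracks[[i]] <- t
  }

  # (2) confidence split
  det <- as.data.frame(detections)
  n_det <- nrow(det)
  hi <- which(det$score >= cfg$track_high_thresh)
  lo <- which(det$score >= cfg$track_low_thresh & det$score < cfg$track_high_thresh)
  det_boxes <- if (n_det) as.matrix(det[, c("x", "y", "w", "h")]) else matrix(numeric(), 0L, 4L)

  sig_cache <- vector("list", n_det)   # each slot: list(sig) or list() for NULL
  sig_of <- function(j) {
    if (is.null(gframe)) return(NULL)
    if (is.null(sig_cache[[j]])) {
      v <- .signature(trk, gframe, det_boxes[j, ])
      sig_cache[[j]] <<- if (is.null(v)) list() else list(v)
    }
    if (length(sig_cache[[j]])) sig_cache[[j]][[1]] else NULL
  }
  app_ready <- function() cfg$use_appearance && !is.null(gframe) && !is.null(trk$codebook)

  # feed the codebook pool early from high-confidence crops
  if (cfg$use_appearance && !is.null(gframe) && is.null(trk$codebook))
    for (j in hi) sig_of(j)

  pred_boxes <- function(idx) {
    if (!length(idx)) return(matrix(numeric(), 0L, 4L))
    do.call(rbind, lapply(trk$tracks[idx], function(t) t$pred_box))
  }

  matched <- matrix(integer(), ncol = 2L)  # (track index, detection index)
  anchor <- NULL

  # (3) stage A: IoU association of high-confidence detections
  candA <- live
  resA <- associate(1 - iou_matrix(pred_boxes(candA), det_boxes[hi, , drop = FALSE]),
                    gate = cfg$match_thresh)
  if (nrow(resA$matches)) {
    pairsA <- cbind(candA[resA$matches[, 1]], hi[resA$matches[, 2]])
    matched <- rbind(matched, pairsA)
    # anchor for displacement validation: the highest-IoU matched pair;
    # displacement is measured per frame from the last observed center
    best <- which.min(1 - vapply(seq_len(nrow(pairsA)), function(r)
      iou(trk$tracks[[pairsA[r, 1]]]$pred_box, det_boxes[pairsA[r, 2], ]),
      numeric(1)))
    a <- pairsA[best, ]
    at <- trk$tracks[[a[1]]]
    agap <- at$frames_since_seen + 1L
    anchor <- list(track = c(0, 0),
                   detection = (box_center(det_boxes[a[2], ]) - at$last_center) / agap)
  }
  left_tracks <- candA[resA$unmatched_rows]
  left_hi <- hi[resA$unmatched_cols]

  # (3b) rematch A: VLAD appearance on stage-A leftovers
  rem <- .appearance_rematch(trk, left_tracks, left_hi, det_boxes, sig_of,
                             app_ready(), anchor, gframe)
  matched <- rbind(matched, rem$pairs)
  left_tracks <- rem$tracks; left_hi <- rem$dets

  # (4) stage B: IoU association of low-confidence detections
  resB <- associate(1 - iou_matrix(pred_boxes(left_tracks),
                                   det_boxes[lo, , drop = FALSE]),
                    gate = cfg$match_thresh)
  if (nrow(resB$matches))
    matched <- rbind(matched, cbind(left_tracks[resB$matches[, 1]],
                                    lo[resB$matches[, 2]]))
  left_tracks <- left_tracks[resB$unmatched_rows]
  left_lo <- lo[resB$unmatched_cols]

  # (4b) rematch B: appearance on stage-B leftovers
  rem <- .appearance_rematch(trk, left_tracks, left_lo, det_boxes, sig_of,
                             app_ready(), anchor, gframe)
  matched <- rbind(matched, rem$pairs)
  left_tracks <- rem$tracks

  # (5) measurement updates and lifecycle
  out <- list()
  for (r in seq_len(nrow(matched))) {
    i <- matched[r, 1]; j <- matched[r, 2]
    t <- trk$tracks[[i]]
    box <- det_boxes[j, ]
    t$kf <- kalman_update(t$kf, box)
    t$frames_since_seen <- 0L
    t$hits <- t$hits + 1L
    if (t$status == "tentative" && t$hits >= 2L) {
      t$track_id <- trk$next_id
      trk$next_id <- trk$next_id + 1L
      t$status <- "active"
    } else if (t$status != "tentative") {
      t$status <- "active"
    }
    t$last_center <- box_center(box)
    # refresh appearance only from confident, well-visible detections so a
    # shrinking occlusion sliver does not pollute the stored gallery; the
    # gallery keeps the best-scoring view plus the most recent one
    if (app_ready() && det$score[j] >= cfg$new_track_thresh) {
      sig <- sig_of(j)
      if (!is.null(sig) && !is_degenerate(sig)) {
        t$app_recent <- sig
        if (det$score[j] >= (t$best_score %||% -Inf)) {
          t$app_best <- sig
          t$best_score <- det$score[j]
        }
        t$app_center <- box_center(box)
      }
    }
    trk$tracks[[i]] <- t
    if (!is.na(t$track_id))
      out[[length(out) + 1L]] <- data.frame(
        frame = frame_index, id = t$track_id, x = box[[1]], y = box[[2]],
        w = box[[3]], h = box[[4]], score = det$score[j])
  }
  for (i in left_tracks) {
    t <- trk$tracks[[i]]
    if (t$status == "tentative") {
      t$status <- "removed"
    } else {
      t$status <- "lost"
      t$hits <- 0L
      t$frames_since_seen <- t$frames_since_seen + 1L
      if (t$frames_since_seen > cfg$track_buffer) t$status <- "removed"
    }
    trk$tracks[[i]] <- t
  }
  # new tentative tracks from unmatched confident detections; on the very
  # first processed frame they are confirmed immediately (there is no earlier
  # frame that could corroborate them)
  for (j in setdiff(left_hi, matched[, 2])) {
    if (det$score[j] < cfg$new_track_thresh) next
    box <- det_boxes[j, ]
    t <- list(kf = kalman_init(box), status = "tentative", track_id = NA_integer_,
              hits = 1L, frames_since_seen = 0L, app_recent = NULL,
              app_best = NULL, best_score = NULL,
              app_center = NULL, last_center = box_center(box),
              pred_box = bbox(box[1], box[2], box[3], box[4]),
              start_frame = frame_index)
    if (first_step) {
      t$status <- "active"
      t$track_id <- trk$next_id
      trk$next_id <- trk$next_id + 1L
      out[[length(out) + 1L]] <- data.frame(
        frame = frame_index, id = t$track_id, x = box[[1]], y = box[[2]],
        w = box[[3]], h = box[[4]], score = det$score[j])
    }
    if (app_ready()) {
      sig <- sig_of(j)
      if (!is.null(sig) && !is_degenerate(sig)) {
        t$app_recent <- sig
        t$app_best <- sig
        t$best_score <- det$score[j]
        t$app_center <- box_center(box)
      }
    }
    trk$tracks[[length(trk$tracks) + 1L]] <- t
  }

  trk$prev_frame <- gframe
  trk$frame_index <- frame_index
  invisible(if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), id = integer(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric(), score = numeric()))
}

# Appearance rematch of leftover tracks x leftover detections: cosine
# distance on VLAD signatures gated at appearance_thresh, then the
# displacement-consistency validation against the stage-A anchor. Degenerate
# signatures never match.
.appearance_rematch <- function(trk, track_idx, det_idx, det_boxes, sig_of,
                                ready, anchor, frame) {
  none <- list(pairs = matrix(integer(), ncol = 2L),
               tracks = track_idx, dets = det_idx)
  if (!ready || !length(track_idx) || !length(det_idx)) return(none)
  has_app <- vapply(trk$tracks[track_idx],
                    function(t) !is.null(t$app_recent) || !is.null(t$app_best),
                    logical(1))
  tcand <- track_idx[has_app]
  if (!length(tcand)) return(none)
  cfg <- trk$config
  cost <- matrix(Inf, length(tcand), length(det_idx))
  for (jj in seq_along(det_idx)) {
    sig <- sig_of(det_idx[jj])
    if (is.null(sig) || is_degenerate(sig)) next
    for (ii in seq_along(tcand)) {
      t <- trk$tracks[[tcand[ii]]]
      sims <- c(if (!is.null(t$app_best)) appearance_similarity(t$app_best, sig),
                if (!is.null(t$app_recent)) appearance_similarity(t$app_recent, sig))
      sims <- sims[!is.na(sims)]
      if (length(sims)) cost[ii, jj] <- 1 - max(sims)
    }
  }
  big <- 10
  cost[!is.finite(cost)] <- big
  trk$stats["rematch_tried"] <- trk$stats["rematch_tried"] + 1L
  res <- associate(cost, gate = cfg$appearance_thresh)
  if (!nrow(res$matches)) return(none)
  trk$stats["rematch_gated"] <- trk$stats["rematch_gated"] + nrow(res$matches)
  tol <- max(5, cfg$displacement_tol * ncol(frame) / 1920)
  ok <- logical(nrow(res$matches))
  for (r in seq_len(nrow(res$matches))) {
    i <- tcand[res$matches[r, 1]]; j <- det_idx[res$matches[r, 2]]
    t <- trk$tracks[[i]]
    gap <- t$frames_since_seen + 1L
    cand <- list(track = c(0, 0),
                 detection = (box_center(det_boxes[j, ]) - t$last_center) / gap)
    ok[r] <- validate_match(cand, anchor, tolerance = tol)
  }
  if (!any(ok)) return(none)
  trk$stats["rematch_accepted"] <- trk$stats["rematch_accepted"] + sum(ok)
  pairs <- cbind(tcand[res$matches[ok, 1]], det_idx[res$matches[ok, 2]])
  list(pairs = pairs,
       tracks = setdiff(track_idx, pairs[, 1]),
       dets = setdiff(det_idx, pairs[, 2]))
}

#' Number of fruit counted so far
#'
#' The count is the highest confirmed track id ever issued; ids are
#' sequential from 1, so this equals the number of confirmed tracks.
#'
#' @param x a `fruit_tracker` or a `fruit_tracks` result
#' @return Nonnegative integer count.
#' @export
fruit_count <- function(x) UseMethod("fruit_count")

#' @export
fruit_count.fruit_tracker <- function(x) x$next_id - 1L

#' @export
fruit_count.fruit_tracks <- function(x) x$count

#' Track fruit through a whole video
#'
#' The main entry point: runs the online tracker over every frame and
#' returns the track ledger and the fruit count (the maximum confirmed track
#' id).
#'
#' @param detections data frame of all detections with columns
#'   `frame, x, y, w, h, score` (1-based frame indices), e.g. from
#'   [read_mot()] or [corrupt_detections()]
#' @param frames optional frames: a list of RGB arrays, or a function
#'   `f(t)` returning frame `t`; required for camera-motion compensation and
#'   appearance rematching
#' @param config a [tracker_config()]
#' @param n_frames number of frames to process; defaults to the largest
#'   detection frame index (or the length of `frames` when it is a list)
#' @return An object of class `fruit_tracks`: a list with `results` (MOT-style
#'   data frame of confirmed-track boxes), `count`, `n_frames`, `config`, and
#'   the final `tracker` state. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @examples
#' scene <- simulate_orchard(scene_config(n_apples = 5, n_frames = 10,
#'                                        frame_size = c(160, 120)))
#' det <- corrupt_detections(scene$gt, corruption_config(miss_prob = 0,
#'                           jitter_sigma = 0, fp_rate = 0))
#' tr <- track_fruits(det, frames = scene$frame,
#'                    config = tracker_config(gmc = "none"))
#' fruit_count(tr)
#' @export
track_fruits <- function(detections, frames = NULL, config = tracker_config(),
                         n_frames = NULL) {
  detections <- as.data.frame(detections)
  if (is.null(n_frames)) {
    n_frames <- max(if (nrow(detections)) max(detections$frame) else 0L,
                    if (is.list(frames)) length(frames) else 0L)
  }
  if (n_frames < 1L) stop_validation("no frames to process")
  get_frame <- function(t) {
    if (is.null(frames)) NULL
    else if (is.function(frames)) frames(t)
    else if (t <= length(frames)) frames[[t]] else NULL
  }
  trk <- new_tracker(config)
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    det_t <- detections[detections$frame == t, , drop = FALSE]
    rows[[t]] <- tracker_step(trk, det_t, frame = get_frame(t), frame_index = t)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, count = fruit_count(trk),
                 n_frames = n_frames, config = config, tracker = trk),
            class = "fruit_tracks")
}
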