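#' Count the fruit in one video
#'
#' The end-to-end counting channel: runs the tracker over all frames of a
#' video and reports the count (the maximum confirmed track id), optionally
#' evaluated against ground truth.
#'
#' @param detections detections data frame `frame, x, y, w, h, score`
#' @param frames optional frames (list of arrays or function `f(t)`)
#' @param config a [tracker_config()]
#' @param gt optional ground-truth data frame for MOTA/IDS evaluation
#' @param video a label for the report
#' @param n_frames number of frames (see [track_fruits()])
#' @return A list of class `count_report`: `video`, `count`, `n_frames`,
#'   `results` (MOT-style data frame), `gt_count`, `mota`, `ids` (when `gt`
#'   given), `config`, and a stable `config_hash`.
#' @export
count_video <- function(detections, frames = NULL, config = tracker_config(),
                        gt = NULL, video = "video", n_frames = NULL) {
  tr <- track_fruits(detections, frames = frames, config = config,
                     n_frames = n_frames)
  rep <- list(video = video, count = tr$count, n_frames = tr$n_frames,
              results = tr$results, config = config,
              config_hash = config_hash(config))
  if (!is.null(gt)) {
    rep$gt_count <- length(unique(gt$id))
    ev <- match_and_tally(gt, tr$results)
    rep$mota <- ev$mota
    rep$ids <- ev$ids
  }
  structure(rep, class = "count_report")
}

# Stable digest of a configuration: md5 of its canonical YAML serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Aggregate tracking and counting evaluation over several videos
#'
#' Pools the per-frame tallies for an overall MOTA, sums identity switches,
#' computes the mean relative counting error, and (given at least two
#' distinct true counts) fits predicted against true counts by least squares.
#'
#' @param videos a list; each element is a list with `gt` (ground-truth data
#'   frame), `results` (tracker output data frame), `count` (predicted) and
#'   optionally `gt_count` (defaults to the number of distinct gt ids)
#' @return A list with `mota`, `ids`, `mae`, `counts` (per-video data frame),
#'   and `fit` (`c(slope, intercept, r2)` or `NULL`).
#' @export
evaluate_suite <- function(videos) {
  if (!length(videos)) stop_validation("need at least one video")
  tallies <- list(); counts <- list()
  for (i in seq_along(videos)) {
    v <- videos[[i]]
    ev <- match_and_tally(v$gt, v$results)
    tallies[[i]] <- ev$tally
    counts[[i]] <- data.frame(video = i,
                              gt = v$gt_count %||% length(unique(v$gt$id)),
                              y = v$count, ids = ev$ids, mota = ev$mota)
  }
  tally <- do.call(rbind, tallies)
  counts <- do.call(rbind, counts)
  fit <- if (length(unique(counts$gt)) >= 2L)
    linear_fit_r2(counts$gt, counts$y) else NULL
  list(mota = mota(tally), ids = sum(counts$ids),
       mae = mae(counts$y, counts$gt), counts = counts, fit = fit)
}

#' Write a scene to a directory (frames, ground truth, detections, config)
#'
#' Writes PNG frames (requires the `png` package), `gt.txt` and `det.txt` in
#' MOT layout, and the resolved scene configuration as YAML.
#'
#' @param scene an `orchard_scene` from [simulate_orchard()]
#' @param dir output directory (created if missing)
#' @param corruption a [corruption_config()] for `det.txt`
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, corruption = corruption_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("writing PNG frames requires the 'png' package")
  n <- scene$config$n_frames
  for (t in seq_len(n))
    png::writePNG(scene$frame(t),
                  file.path(dir, sprintf("frame_%04d.png", t)))
  write_mot(scene$gt, file.path(dir, "gt.txt"), kind = "ground_truth")
  det <- corrupt_detections(scene$gt, corruption,
                            frame_size = scene$config$frame_size)
  write_mot(det, file.path(dir, "det.txt"), kind = "detections")
  writeLines(yaml::as.yaml(unclass(scene$config)), file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Read frames from a directory of PNG images
#'
#' @param dir directory containing `frame_*.png` files (lexicographic order)
#' @return A function `f(t)` returning frame `t` as an array.
#' @export
read_frames <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("reading PNG frames requires the 'png' package")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  function(t) png::readPNG(files[[t]])
}

#' Write a count report as JSON
#'
#' @param report a `count_report` (or a plain named list)
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_count_report <- function(report, path) {
  keep <- setdiff(names(report), c("results", "config"))
  obj <- unclass(report)[keep]
  obj$config <- unclass(report$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
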