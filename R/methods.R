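#' @export
print.fruit_tracks <- function(x, ...) {
  cat("Fruit tracking result\n")
  cat("  frames processed :", x$n_frames, "\n")
  cat("  confirmed tracks :", x$count, "\n")
  cat("  output rows      :", nrow(x$results), "\n")
  cat("  appearance stages:",
      if (x$config$use_appearance) "enabled" else "disabled", "\n")
  invisible(x)
}

#' @export
summary.fruit_tracks <- function(object, ...) {
  res <- object$results
  lens <- if (nrow(res)) table(res$id) else integer()
  out <- list(count = object$count, n_frames = object$n_frames,
              mean_track_length = if (length(lens)) mean(lens) else NA_real_,
              median_track_length = if (length(lens)) stats::median(lens) else NA_real_,
              config = object$config)
  class(out) <- "summary.fruit_tracks"
  out
}

#' @export
print.summary.fruit_tracks <- function(x, ...) {
  cat("Fruit tracking summary\n")
  cat("  count               :", x$count, "\n")
  cat("  frames              :", x$n_frames, "\n")
  cat("  mean track length   :", round(x$mean_track_length, 1), "frames\n")
  cat("  median track length :", x$median_track_length, "frames\n")
  invisible(x)
}

#' @export
as.data.frame.fruit_tracks <- function(x, ...) x$results

#' Plot fruit trajectories
#'
#' Draws each confirmed track's center trajectory in image coordinates
#' (y axis flipped to match image orientation).
#'
#' @param x a `fruit_tracks` object
#' @param ... passed to [graphics::plot()]
#' @export
plot.fruit_tracks <- function(x, ...) {
  res <- x$results
  if (!nrow(res)) {
    graphics::plot(0, 0, type = "n", xlab = "x", ylab = "y",
                   main = "no confirmed tracks")
    return(invisible(x))
  }
  cx <- res$x + res$w / 2
  cy <- res$y + res$h / 2
  graphics::plot(range(cx), rev(range(cy)), type = "n", xlab = "x (px)",
                 ylab = "y (px)", ylim = rev(range(cy)),
                 main = sprintf("%d tracks over %d frames", x$count, x$n_frames),
                 ...)
  cols <- grDevices::hcl.colors(max(res$id), "Dark 3")
  for (id in unique(res$id)) {
    sel <- res$id == id
    graphics::lines(cx[sel][order(res$frame[sel])],
                    cy[sel][order(res$frame[sel])], col = cols[id])
  }
  invisible(x)
}

#' @export
print.count_report <- function(x, ...) {
  cat("Count report:", x$video, "\n")
  cat("  predicted count :", x$count, "\n")
  if (!is.null(x$gt_count)) {
    cat("  true count      :", x$gt_count, "\n")
    cat("  MOTA            :", round(x$mota, 4), "\n")
    cat("  ID switches     :", x$ids, "\n")
  }
  cat("  config hash     :", x$config_hash, "\n")
  invisible(x)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("Tracker configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.orchard_scene <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic orchard scene\n")
  cat("  fruit      :", cfg$n_apples, "\n")
  cat("  frames     :", cfg$n_frames, "@", cfg$frame_size[1], "x",
      cfg$frame_size[2], "px\n")
  cat("  camera pan :", paste(cfg$camera_velocity, collapse = ", "), "px/frame\n")
  cat("  occluders  :", length(cfg$occluders), "\n")
  cat("  gt rows    :", nrow(x$gt), "\n")
  invisible(x)
}
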