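#' Height-estimation configuration
#'
#' @param outlier_k MAD multiplier for depth outlier rejection (default 3).
#' @param min_points Minimum surviving points for a height estimate
#'   (default 20).
#' @param smoothing_window Frames in the per-track running median of
#'   reported heights (default 5).
#' @param shrink_fraction Central box fraction sampled for depth
#'   (default 0.8), trimming edge/background pixels.
#' @param use_camera_y If TRUE the median is taken over camera-frame y
#'   instead of ground-frame heights (comparison mode; default FALSE --
#'   only the ground-frame median yields an absolute height above ground
#'   after the extrinsic transform).
#' @return An object of class `height_config`.
#' @export
height_config <- function(outlier_k = 3, min_points = 20L,
                          smoothing_window = 5L, shrink_fraction = 0.8,
                          use_camera_y = FALSE) {
  stopifnot(outlier_k > 0, min_points >= 1, smoothing_window >= 1)
  structure(list(outlier_k = outlier_k, min_points = as.integer(min_points),
                 smoothing_window = as.integer(smoothing_window),
                 shrink_fraction = shrink_fraction,
                 use_camera_y = use_camera_y),
            class = "height_config")
}

#' Remove depth outliers from a point cloud
#'
#' Keeps points whose depth lies within `outlier_k` median absolute
#' deviations of the median depth; the MAD is floored at 1 mm so a
#' constant-depth patch keeps all its points.
#'
#' @param points n x 3 camera-frame point matrix (meters).
#' @param cfg A [height_config()].
#' @return The filtered point matrix. Fewer than `min_points` survivors
#'   raise an "insufficient points" error.
#' @export
remove_depth_outliers <- function(points, cfg = height_config()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) == 0L) stop("empty point cloud")
  z <- points[, 3]
  med <- stats::median(z)
  madz <- max(stats::mad(z, constant = 1), 0.001)
  keep <- abs(z - med) <= cfg$outlier_k * madz
  if (sum(keep) < cfg$min_points)
    stop("insufficient points: ", sum(keep), " after outlier removal")
  points[keep, , drop = FALSE]
}

#' Estimate ear height above ground for one tracked box
#'
#' Back-projects the valid depth pixels of the centrally shrunk box,
#' removes depth outliers, transforms each point to its height above
#' ground with the camera extrinsics, and reports the median (even counts
#' take the mean of the middle two).
#'
#' @param box Pixel rectangle `c(x1, y1, x2, y2)`.
#' @param depth A [depth_frame()].
#' @param cam A [camera_model()].
#' @param cfg A [height_config()].
#' @return A list: `height_m`, `n_points_used`, `n_outliers_removed`,
#'   `box_depth_m`. Insufficient valid points raise an error (callers skip
#'   the frame).
#' @export
estimate_height <- function(box, depth, cam, cfg = height_config()) {
  cloud <- backproject_box(depth, shrink_box(box, cfg$shrink_fraction), cam)
  n0 <- nrow(cloud$points)
  pts <- remove_depth_outliers(cloud$points, cfg)
  hts <- if (cfg$use_camera_y) cam$mount_height - pts[, 2]
         else ground_height(pts, cam)
  h <- stats::median(hts)
  if (!is.finite(h) || h < 0 || h > cam$mount_height + 1)
    stop("height estimate ", signif(h, 4), " outside sanity band")
  list(height_m = h, n_points_used = nrow(pts),
       n_outliers_removed = n0 - nrow(pts),
       box_depth_m = stats::median(pts[, 3]))
}

#' Smooth and summarize a track's height series
#'
#' Running median over `smoothing_window` frames (centered, shrinking at
#' the ends), plus a robust summary.
#'
#' @param heights Numeric vector of per-frame height estimates (meters).
#' @param cfg A [height_config()].
#' @return List with `smoothed` (same length) and `summary`
#'   (`median`, `mad`, `n`).
#' @export
track_height_series <- function(heights, cfg = height_config()) {
  n <- length(heights)
  stopifnot(n >= 1)
  wd <- cfg$smoothing_window
  half <- (wd - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(heights[lo:hi])
  }, numeric(1))
  list(smoothed = sm,
       summary = list(median = stats::median(heights),
                      mad = stats::mad(heights, constant = 1), n = n))
}

#' Per-frame height estimates for a track table
#'
#' Applies [estimate_height()] to every record of a track output table,
#' reading the matching depth frame per frame. Frames with insufficient
#' depth are skipped.
#'
#' @param tracks Track records (`frame, track_id, x, y, w, h`).
#' @param depth_for_frame Function `(frame) -> depth_frame`.
#' @param cam A [camera_model()].
#' @param cfg A [height_config()].
#' @return Data.frame `track_id, frame, height_m, n_points, box_depth_m`.
#' @export
estimate_track_heights <- function(tracks, depth_for_frame, cam,
                                   cfg = height_config()) {
  out <- vector("list", nrow(tracks))
  frames <- sort(unique(tracks$frame))
  for (f in frames) {
    dep <- depth_for_frame(f)
    idx <- which(tracks$frame == f)
    for (i in idx) {
      r <- tracks[i, ]
      est <- tryCatch(
        estimate_height(c(r$x, r$y, r$x + r$w, r$y + r$h), dep, cam, cfg),
        error = function(e) NULL)
      if (is.null(est)) next
      out[[i]] <- data.frame(track_id = r$track_id, frame = f,
                             height_m = est$height_m,
                             n_points = est$n_points_used,
                             box_depth_m = est$box_depth_m)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(track_id = integer(0), frame = integer(0),
                      height_m = numeric(0), n_points = integer(0),
                      box_depth_m = numeric(0))
  res
}

#' Summarize per-track heights
#'
#' @param heights Output of [estimate_track_heights()].
#' @param cfg A [height_config()].
#' @return Data.frame `track_id, height_median_m, height_mad_m, n_frames`.
#' @export
summarize_track_heights <- function(heights, cfg = height_config()) {
  ids <- sort(unique(heights$track_id))
  do.call(rbind, lapply(ids, function(id) {
    h <- heights$height_m[heights$track_id == id]
    s <- track_height_series(h, cfg)$summary
    data.frame(track_id = id, height_median_m = s$median,
               height_mad_m = s$mad, n_frames = s$n)
  }))
}
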