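#' Configuration for depth-based row filtering
#'
#' Detections from non-target planting rows are removed with a single range
#' threshold. With ~0.6 m row spacing and the platform running along the
#' row, 0.5 m cleanly separates the target row from the next one.
#'
#' @param threshold_m Maximum kept range in meters (default 0.5).
#' @param min_valid_pixels Minimum valid depth pixels per box (default 10).
#' @param shrink_fraction Central fraction of the box used for depth
#'   sampling (default 0.6); ear boxes include background pixels near their
#'   edges, the shrunk center is dominated by the ear surface.
#' @return An object of class `depth_filter_config`.
#' @export
depth_filter_config <- function(threshold_m = 0.5, min_valid_pixels = 10L,
                                shrink_fraction = 0.6) {
  stopifnot(threshold_m > 0, shrink_fraction > 0, shrink_fraction <= 1,
            min_valid_pixels >= 1)
  structure(list(threshold_m = threshold_m,
                 min_valid_pixels = as.integer(min_valid_pixels),
                 shrink_fraction = shrink_fraction),
            class = "depth_filter_config")
}

# shrink a (x1,y1,x2,y2) box about its center by `frac` per side
shrink_box <- function(box, frac) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  hw <- (box[3] - box[1]) / 2 * frac; hh <- (box[4] - box[2]) / 2 * frac
  c(cx - hw, cy - hh, cx + hw, cy + hh)
}

#' Representative depth of a detection box
#'
#' Median of the valid depth values inside the centrally shrunk box; an
#' even count takes the mean of the two middle values.
#'
#' @param depth A [depth_frame()].
#' @param box Pixel rectangle `c(x1, y1, x2, y2)`.
#' @param cfg A [depth_filter_config()].
#' @param cam Optional [camera_model()]; needed only to convert raw units.
#' @return Representative depth in meters. Fewer than `min_valid_pixels`
#'   valid pixels raises an "insufficient depth" error.
#' @export
box_depth <- function(depth, box, cfg = depth_filter_config(), cam = NULL) {
  scale <- if (is.null(cam)) 1000 else cam$depth_scale
  px <- box_pixels(depth, shrink_box(box, cfg$shrink_fraction))
  d <- if (length(px$u)) depth$data[cbind(px$v + 1L, px$u + 1L)] else numeric(0)
  d <- d[is.finite(d) & d > 0]
  if (length(d) < cfg$min_valid_pixels)
    stop("insufficient depth: ", length(d), " valid pixel(s) in box")
  stats::median(d) / scale
}

#' Remove detections from non-target planting rows
#'
#' Each detection gets a representative box depth; it is kept iff its range
#' is at most `threshold_m`. When a camera model is supplied the comparison
#' uses the horizontal ground-plane range ([ground_range()]) of the box
#' center at the representative depth -- for a pitched-down camera this is
#' the quantity that actually separates planting rows, and it reduces to
#' the raw depth for a level camera. Without a camera model the raw
#' camera-frame depth is compared directly. Boxes with insufficient valid
#' depth are kept and flagged: the filter removes confirmed far rows, it
#' does not discard uncertain detections.
#'
#' @param detections Detection data.frame with columns `x, y, w, h`
#'   (top-left + size, pixels); see [read_detections()].
#' @param depth A [depth_frame()] for the same frame.
#' @param cfg A [depth_filter_config()].
#' @param cam Optional [camera_model()] enabling the ground-range comparison.
#' @return A list with `kept` and `removed` data.frames; both carry added
#'   columns `box_depth_m` (NA when insufficient), `range_m` (the compared
#'   quantity) and `depth_flag` (`"ok"` or `"insufficient"`).
#' @export
filter_by_depth <- function(detections, depth, cfg = depth_filter_config(),
                            cam = NULL) {
  n <- nrow(detections)
  dep <- rep(NA_real_, n); rng <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    box <- det_box(detections[i, ])
    d <- tryCatch(box_depth(depth, box, cfg, cam), error = function(e) NA_real_)
    if (is.na(d)) { flag[i] <- "insufficient"; next }
    dep[i] <- d
    rng[i] <- if (is.null(cam)) d else {
      uc <- (box[1] + box[3]) / 2; vc <- (box[2] + box[4]) / 2
      ground_range(backproject_pixel(uc, vc, d * cam$depth_scale, cam), cam)
    }
  }
  detections$box_depth_m <- dep
  detections$range_m <- rng
  detections$depth_flag <- flag
  keep <- is.na(rng) | rng <= cfg$threshold_m
  list(kept = detections[keep, , drop = FALSE],
       removed = detections[!keep, , drop = FALSE])
}

# (x1,y1,x2,y2) box of a detection row in tlwh form
det_box <- function(det) {
  c(det$x, det$y, det$x + det$w, det$y + det$h)
}
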