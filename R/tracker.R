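#' Tracker configuration
#'
#' DeepSORT-style association settings. The matching cascade prioritizes
#' recently updated tracks, costs come from appearance (embedding cosine
#' distance) gated by the Mahalanobis distance under the filter's
#' confidence-adaptive innovation covariance; tracks without embedding
#' support fall back to motion-only matching.
#'
#' @param n_init Consecutive hits before a track is confirmed (default 3).
#' @param max_age Frames a track may coast unmatched before deletion
#'   (default 30).
#' @param gating_chi2 Mahalanobis gate, chi-square 0.95 quantile at 4
#'   degrees of freedom (default 9.4877).
#' @param max_cosine_distance Appearance gate (default 0.2).
#' @param iou_threshold Minimum IoU for the fallback IoU match (default 0.3).
#' @param gallery_size Embedding ring-buffer capacity per track (default 100).
#' @param filter A [filter_params()] for the state estimator.
#' @param adaptive Use the confidence-adaptive observation noise
#'   (default TRUE); FALSE reverts to the fixed-noise baseline filter.
#' @param smooth Apply center smoothing to reported boxes (default TRUE).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(n_init = 3L, max_age = 30L, gating_chi2 = 9.4877,
                           max_cosine_distance = 0.2, iou_threshold = 0.3,
                           gallery_size = 100L, filter = filter_params(),
                           adaptive = TRUE, smooth = TRUE) {
  stopifnot(n_init >= 1, max_age >= 1, gating_chi2 > 0,
            max_cosine_distance > 0, iou_threshold > 0)
  structure(list(n_init = as.integer(n_init), max_age = as.integer(max_age),
                 gating_chi2 = gating_chi2,
                 max_cosine_distance = max_cosine_distance,
                 iou_threshold = iou_threshold,
                 gallery_size = as.integer(gallery_size),
                 filter = filter, adaptive = adaptive, smooth = smooth),
            class = "tracker_config")
}

#' Create an empty tracker
#'
#' @param cfg A [tracker_config()].
#' @return A `tracker` object holding live tracks and the id counter.
#' @export
new_tracker <- function(cfg = tracker_config()) {
  structure(list(cfg = cfg, tracks = list(), next_id = 1L), class = "tracker")
}

new_track <- function(id, z, conf, embedding, cfg) {
  list(id = id, state = kf_initiate(z, cfg$filter),
       status = "tentative", hits = 1L, age = 1L, time_since_update = 0L,
       conf = conf,
       gallery = if (is.null(embedding)) list() else list(embedding))
}

# observation vector (x, y, a, h) from a tlwh detection row
det_xyah <- function(det) {
  c(det$x + det$w / 2, det$y + det$h / 2, det$w / det$h, det$h)
}

det_embedding <- function(det) {
  cols <- grep("^e[0-9]+$", names(det), value = TRUE)
  if (!length(cols)) return(NULL)
  e <- as.numeric(det[1, cols])
  if (all(is.na(e))) return(NULL)
  e
}

#' Squared Mahalanobis gating distance between a track and a detection
#'
#' Innovation whitened by `H P H^T + R_t`, with `R_t` the adaptive
#' observation noise for this detection's confidence: low-confidence
#' detections get larger `R_t` and hence a looser gate.
#'
#' @param track A track entry of a [new_tracker()] (predicted to the
#'   current frame).
#' @param det One-row detection data.frame.
#' @param cfg A [tracker_config()].
#' @return Squared Mahalanobis distance (scalar).
#' @export
gating_distance <- function(track, det, cfg = tracker_config()) {
  p <- cfg$filter
  z <- det_xyah(det)
  h_prev <- max(track$state$mean[4], 1)
  R <- if (cfg$adaptive) adaptive_noise(det$conf, h_prev, p)
       else fixed_noise(h_prev, p)
  S <- p$H %*% track$state$cov %*% t(p$H) + R
  innov <- z - drop(p$H %*% track$state$mean)
  drop(t(innov) %*% solve(S, innov))
}

#' Appearance cosine distance between a track gallery and a detection
#'
#' Minimum over the gallery of `1 - <e_gallery, e_det>` for unit-norm
#' embeddings; in [0, 2]. `NA` when either side lacks embeddings.
#'
#' @inheritParams gating_distance
#' @return Cosine distance, or `NA_real_` if appearance is unavailable.
#' @export
appearance_distance <- function(track, det, cfg = tracker_config()) {
  e <- det_embedding(det)
  if (is.null(e) || !length(track$gallery)) return(NA_real_)
  min(vapply(track$gallery, function(g) 1 - sum(g * e), numeric(1)))
}

box_iou <- function(a, b) {
  # a, b: c(x1, y1, x2, y2)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

state_tlbr <- function(state, smoothed = TRUE) {
  ctr <- if (smoothed) state$smoothed else state$mean[1:2]
  a <- state$mean[3]; h <- state$mean[4]; w <- a * h
  c(ctr[1] - w / 2, ctr[2] - h / 2, ctr[1] + w / 2, ctr[2] + h / 2)
}

# cost matrix for a set of tracks vs detections; appearance when available,
# otherwise normalized Mahalanobis; Inf where either gate fails
cascade_cost <- function(tracks, detections, cfg) {
  nt <- length(tracks); nd <- nrow(detections)
  cost <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) {
      d2 <- gating_distance(tracks[[i]], detections[j, ], cfg)
      if (d2 > cfg$gating_chi2) next
      ad <- appearance_distance(tracks[[i]], detections[j, ], cfg)
      if (!is.na(ad)) {
        if (ad <= cfg$max_cosine_distance) cost[i, j] <- ad
      } else {
        cost[i, j] <- d2 / cfg$gating_chi2
      }
    }
  }
  cost
}

#' Associate predicted tracks with current detections
#'
#' Matching cascade: confirmed tracks are matched in order of increasing
#' time since update (most recently seen first), using appearance cost
#' under the Mahalanobis gate; remaining age-1 and tentative tracks then
#' get an IoU match against leftover detections. Assignment at each stage
#' minimizes total cost via the Hungarian algorithm; ties resolve to the
#' lowest track id, then lowest detection index.
#'
#' @param tracks List of track entries, predicted to the current frame.
#' @param detections Detection data.frame for the frame.
#' @param cfg A [tracker_config()].
#' @return A list with `matches` (2-column matrix of track index /
#'   detection row), `unmatched_tracks`, `unmatched_detections` (indices).
#' @export
associate <- function(tracks, detections, cfg = tracker_config()) {
  nt <- length(tracks); nd <- if (is.null(detections)) 0L else nrow(detections)
  matches <- matrix(integer(0), ncol = 2)
  if (nt == 0L || nd == 0L)
    return(list(matches = matches, unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd)))
  ord <- order(vapply(tracks, function(t) t$id, numeric(1)))
  confirmed <- ord[vapply(tracks[ord], function(t) t$status == "confirmed", logical(1))]
  free_det <- seq_len(nd)
  # cascade over age
  for (age in seq_len(cfg$max_age)) {
    if (!length(free_det)) break
    lvl <- confirmed[vapply(tracks[confirmed], function(t)
      t$time_since_update == age, logical(1))]
    if (!length(lvl)) next
    cost <- cascade_cost(tracks[lvl], detections[free_det, , drop = FALSE], cfg)
    asg <- solve_assignment(cost)
    for (k in seq_along(asg)) {
      if (!is.na(asg[k])) {
        matches <- rbind(matches, c(lvl[k], free_det[asg[k]]))
      }
    }
    free_det <- setdiff(free_det, matches[, 2])
  }
  # IoU fallback: tentative tracks and confirmed tracks missed exactly once
  matched_tr <- matches[, 1]
  iou_cand <- ord[vapply(tracks[ord], function(t)
    t$status == "tentative" || t$time_since_update == 1L, logical(1))]
  iou_cand <- setdiff(iou_cand, matched_tr)
  if (length(iou_cand) && length(free_det)) {
    cost <- matrix(Inf, length(iou_cand), length(free_det))
    for (i in seq_along(iou_cand)) {
      tb <- state_tlbr(tracks[[iou_cand[i]]]$state, smoothed = FALSE)
      for (j in seq_along(free_det)) {
        db <- det_box(detections[free_det[j], ])
        iou <- box_iou(tb, db)
        if (iou >= cfg$iou_threshold) cost[i, j] <- 1 - iou
      }
    }
    asg <- solve_assignment(cost)
    for (k in seq_along(asg)) {
      if (!is.na(asg[k]))
        matches <- rbind(matches, c(iou_cand[k], free_det[asg[k]]))
    }
    free_det <- setdiff(free_det, matches[, 2])
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1]),
       unmatched_detections = free_det)
}

#' Advance the tracker by one frame
#'
#' Predict all tracks, associate, update matched tracks through the
#' adaptive filter (with center smoothing), initiate tracks from unmatched
#' detections, age and delete stale tracks. Emits one output record per
#' matched track (including tentative ones, tagged by `status`).
#'
#' @param tracker A [new_tracker()].
#' @param detections Detection data.frame for this frame (may be empty or
#'   NULL).
#' @param frame Frame index (0-based internally).
#' @return A list with the updated `tracker` and `records`, a data.frame
#'   `frame, track_id, x, y, w, h, conf, status` (tlwh pixels, smoothed
#'   center).
#' @export
track_frame <- function(tracker, detections, frame) {
  cfg <- tracker$cfg
  tracker$tracks <- lapply(tracker$tracks, function(t) {
    t$state <- kf_predict(t$state, cfg$filter)
    t$age <- t$age + 1L
    t$time_since_update <- t$time_since_update + 1L
    t
  })
  nd <- if (is.null(detections)) 0L else nrow(detections)
  res <- associate(tracker$tracks, detections, cfg)
  # updates
  if (nrow(res$matches)) {
    for (k in seq_len(nrow(res$matches))) {
      ti <- res$matches[k, 1]; dj <- res$matches[k, 2]
      det <- detections[dj, ]
      t <- tracker$tracks[[ti]]
      z <- det_xyah(det)
      h_prev <- max(t$state$mean[4], 1)
      R <- if (cfg$adaptive) adaptive_noise(det$conf, h_prev, cfg$filter)
           else fixed_noise(h_prev, cfg$filter)
      t$state <- kf_update(t$state, z, R, cfg$filter)
      if (cfg$smooth) {
        carried <- t$state$smoothed + t$state$mean[5:6]
        t$state$smoothed <- smooth_center(carried, t$state$mean[1:2],
                                          cfg$filter$alpha)
      } else t$state$smoothed <- t$state$mean[1:2]
      e <- det_embedding(det)
      if (!is.null(e)) {
        t$gallery <- c(t$gallery, list(e))
        if (length(t$gallery) > cfg$gallery_size)
          t$gallery <- t$gallery[-1]
      }
      t$hits <- t$hits + 1L
      t$time_since_update <- 0L
      t$conf <- det$conf
      if (t$status == "tentative" && t$hits >= cfg$n_init)
        t$status <- "confirmed"
      tracker$tracks[[ti]] <- t
    }
  }
  # lifecycle
  drop_idx <- integer(0)
  for (ti in res$unmatched_tracks) {
    t <- tracker$tracks[[ti]]
    if (t$status == "tentative" || t$time_since_update > cfg$max_age)
      drop_idx <- c(drop_idx, ti)
  }
  if (length(drop_idx)) tracker$tracks <- tracker$tracks[-drop_idx]
  # initiations
  for (dj in res$unmatched_detections) {
    det <- detections[dj, ]
    z <- det_xyah(det)
    if (z[4] <= 0 || z[3] <= 0) next
    tracker$tracks <- c(tracker$tracks,
                        list(new_track(tracker$next_id, z, det$conf,
                                       det_embedding(det), cfg)))
    tracker$next_id <- tracker$next_id + 1L
  }
  # emit records for tracks updated this frame
  recs <- lapply(tracker$tracks, function(t) {
    if (t$time_since_update != 0L) return(NULL)
    b <- state_tlbr(t$state, smoothed = cfg$smooth)
    data.frame(frame = frame, track_id = t$id,
               x = b[1], y = b[2], w = b[3] - b[1], h = b[4] - b[2],
               conf = t$conf, status = t$status)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(frame = integer(0), track_id = integer(0),
                       x = numeric(0), y = numeric(0), w = numeric(0),
                       h = numeric(0), conf = numeric(0),
                       status = character(0))
  list(tracker = tracker, records = recs)
}

#' Run the tracker over a full detection sequence
#'
#' @param detections Detection data.frame with a 0-based `frame` column.
#' @param n_frames Number of frames to process (defaults to
#'   `max(frame) + 1`).
#' @param cfg A [tracker_config()].
#' @return Track records data.frame (see [track_frame()]).
#' @export
run_tracker <- function(detections, n_frames = NULL, cfg = tracker_config()) {
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  tracker <- new_tracker(cfg)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    step <- track_frame(tracker, dets, f)
    tracker <- step$tracker
    out[[f + 1L]] <- step$records
  }
  do.call(rbind, out)
}
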