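#' Synthetic field-scene configuration
#'
#' Describes a two-row corn scene viewed from a moving RGB-D platform: the
#' camera travels along the row at `camera_speed_m_per_frame`, side-looking
#' and pitched down, with the target row at `lateral_offset_m` and a far
#' row one row spacing beyond. Ears are placed along each row with uniform
#' heights in `ear_height_range_m` and rendered into depth frames as
#' constant-depth rectangles (the pipeline only consumes in-box depth
#' statistics). Detections carry confidence-dependent Gaussian box noise
#' with std `kappa * (1 - c) * true_h`, the same law the adaptive filter's
#' observation-noise model assumes.
#'
#' @param n_ears_target_row,n_ears_far_row Ear counts per row.
#' @param row_spacing_m Planting row spacing (default 0.6 m).
#' @param lateral_offset_m Camera-to-target-row horizontal distance
#'   (default 0.4 m, within the platform's 30-50 cm working offset).
#' @param ear_height_range_m Uniform range of true ear heights
#'   (default 0.8-1.5 m).
#' @param camera A [camera_model()] (default: 1.8 m mount, 45 deg pitch).
#' @param frames Number of frames.
#' @param camera_speed_m_per_frame Platform advance per frame (default
#'   0.02 m, about 0.6 m/s at 30 fps).
#' @param ear_spacing_m Mean along-row spacing between ears (default 0.3 m).
#' @param occlusion_windows List of occlusion episodes, each
#'   `list(ids =, from =, to =, mode = "drop"|"degrade")` (frames 0-based,
#'   inclusive): `drop` removes the detection, `degrade` forces confidence
#'   to the low end of `confidence_range` and triples the box noise.
#' @param kappa Box-noise scale in std `= kappa (1 - c) h` (default 0.05,
#'   matching the filter's position normalization weight).
#' @param confidence_range Detection confidence is drawn uniformly from
#'   this range (default `c(0.4, 0.9)`).
#' @param depth_noise_frac Multiplicative Gaussian depth noise (default 0.01).
#' @param bg_contamination_frac Fraction of in-box depth pixels replaced
#'   by background depth (default 0.2).
#' @param fp_rate Expected false positives per frame (default 0).
#' @param embedding_dim Appearance embedding dimension (default 16).
#' @param embedding_cluster_std Per-identity embedding cluster spread
#'   (default 0.1).
#' @param background_depth_m Depth assigned to non-ear pixels (default 4 m).
#' @param min_visible_fraction Minimum unclipped, unoccluded box fraction
#'   for an ear to count as visible/detected (default 0.7): heavily
#'   occluded or clipped ears are neither annotated nor detected.
#' @param seed RNG seed for the whole scene.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_ears_target_row = 20L, n_ears_far_row = 0L,
                         row_spacing_m = 0.6, lateral_offset_m = 0.4,
                         ear_height_range_m = c(0.8, 1.5),
                         camera = camera_model(fx = 200, fy = 200,
                                               cx = 159.5, cy = 119.5,
                                               mount_height = 1.8,
                                               pitch_deg = 45),
                         frames = 100L, camera_speed_m_per_frame = 0.02,
                         ear_spacing_m = 0.3,
                         occlusion_windows = list(),
                         kappa = 0.05, confidence_range = c(0.4, 0.9),
                         depth_noise_frac = 0.01,
                         bg_contamination_frac = 0.2,
                         fp_rate = 0, embedding_dim = 16L,
                         embedding_cluster_std = 0.1,
                         background_depth_m = 4,
                         min_visible_fraction = 0.7,
                         seed = 1L) {
  stopifnot(row_spacing_m > 0, frames >= 1,
            depth_noise_frac >= 0, depth_noise_frac <= 1,
            bg_contamination_frac >= 0, bg_contamination_frac <= 1,
            length(ear_height_range_m) == 2)
  structure(as.list(environment()), class = "scene_config")
}

# ear physical size (m): typical fresh-corn ear with husk
EAR_W_M <- 0.09
EAR_H_M <- 0.25

#' Generate scene ground truth
#'
#' Places ears along the two rows, advances the camera, and projects each
#' ear's extent into every frame. Deterministic for a fixed seed.
#'
#' @param cfg A [scene_config()].
#' @return A `scene_ground_truth` list: `ears` (id, world position, true
#'   height, row label, embedding mean) and `boxes` (per frame x ear:
#'   `frame, id, x, y, w, h, z_m, visible`, tlwh pixels, 0-based frames).
#' @export
generate_scene <- function(cfg) {
  rng <- local_rng(cfg$seed)
  n_t <- cfg$n_ears_target_row; n_f <- cfg$n_ears_far_row
  n <- n_t + n_f
  row_y <- c(rep(cfg$lateral_offset_m, n_t),
             rep(cfg$lateral_offset_m + cfg$row_spacing_m, n_f))
  xs <- c(seq_len(n_t), seq_len(max(n_f, 1))[seq_len(n_f)]) * cfg$ear_spacing_m
  xs <- xs + rng$unif(n, -0.05, 0.05)
  hts <- rng$unif(n, cfg$ear_height_range_m[1], cfg$ear_height_range_m[2])
  emb <- NULL
  if (cfg$embedding_dim > 0) {
    emb <- matrix(rng$norm(n * cfg$embedding_dim), n, cfg$embedding_dim)
    emb <- emb / sqrt(rowSums(emb^2))
  }
  ears <- data.frame(id = seq_len(n), x = xs, y = row_y, height_m = hts,
                     row = rep(c("target", "far"), c(n_t, n_f)))
  cam <- cfg$camera
  boxes <- vector("list", cfg$frames)
  for (f in seq_len(cfg$frames) - 1L) {
    station <- f * cfg$camera_speed_m_per_frame
    ctr <- project_point(cbind(ears$x, ears$y, ears$height_m), cam, station)
    wpx <- cam$fx * EAR_W_M / ctr$z_m
    hpx <- cam$fy * EAR_H_M / ctr$z_m
    x1 <- ctr$u - wpx / 2; y1 <- ctr$v - hpx / 2
    df <- data.frame(frame = f, id = ears$id, x = x1, y = y1,
                     w = wpx, h = hpx, z_m = ctr$z_m,
                     height_m = ears$height_m, row = ears$row)
    df$in_image <- ctr$visible & clipped_fraction(df, cam) >= cfg$min_visible_fraction
    boxes[[f + 1L]] <- df
  }
  boxes <- do.call(rbind, boxes)
  boxes <- boxes[!is.na(boxes$z_m), , drop = FALSE]
  # occlusion by nearer boxes: visible only if mostly unoccluded
  boxes$occluded_frac <- 0
  for (f in unique(boxes$frame)) {
    idx <- which(boxes$frame == f & boxes$in_image)
    if (length(idx) < 2) next
    ord <- idx[order(boxes$z_m[idx])]          # near first
    for (k in seq_along(ord)[-1]) {
      b <- as.numeric(boxes[ord[k], c("x", "y", "w", "h")])
      bb <- c(b[1], b[2], b[1] + b[3], b[2] + b[4])
      occ <- 0
      for (m in seq_len(k - 1)) {
        a <- as.numeric(boxes[ord[m], c("x", "y", "w", "h")])
        ab <- c(a[1], a[2], a[1] + a[3], a[2] + a[4])
        ix <- max(0, min(ab[3], bb[3]) - max(ab[1], bb[1]))
        iy <- max(0, min(ab[4], bb[4]) - max(ab[2], bb[2]))
        occ <- occ + ix * iy
      }
      boxes$occluded_frac[ord[k]] <- min(1, occ / (b[3] * b[4]))
    }
  }
  boxes$visible <- boxes$in_image & boxes$occluded_frac <= 0.3
  structure(list(config = cfg, ears = ears, embeddings = emb, boxes = boxes),
            class = "scene_ground_truth")
}

clipped_fraction <- function(df, cam) {
  x2 <- df$x + df$w; y2 <- df$y + df$h
  cx1 <- pmax(df$x, 0); cy1 <- pmax(df$y, 0)
  cx2 <- pmin(x2, cam$width); cy2 <- pmin(y2, cam$height)
  area <- pmax(0, cx2 - cx1) * pmax(0, cy2 - cy1)
  ifelse(df$w * df$h > 0, area / (df$w * df$h), 0)
}

#' Render the depth frame for one scene frame
#'
#' Background at the far sentinel depth; each visible ear's projected box
#' is filled with its true camera depth, optionally perturbed by
#' multiplicative Gaussian noise, with a configured fraction of in-box
#' pixels replaced by background depth; nearer ears paint over farther
#' ones.
#'
#' @param gt A [generate_scene()] result.
#' @param frame Frame index (0-based).
#' @param cfg The scene's [scene_config()].
#' @param rng Optional [local_rng()] stream; defaults to a frame-derived
#'   child of the scene seed so frames can be rendered independently.
#' @return A [depth_frame()] in raw depth units.
#' @export
render_depth_frame <- function(gt, frame, cfg = gt$config, rng = NULL) {
  if (is.null(rng)) rng <- local_rng(cfg$seed)$spawn(1000L + frame)
  cam <- cfg$camera
  d <- matrix(cfg$background_depth_m * cam$depth_scale, cam$height, cam$width)
  bx <- gt$boxes[gt$boxes$frame == frame & gt$boxes$in_image, , drop = FALSE]
  if (nrow(bx)) {
    bx <- bx[order(-bx$z_m), , drop = FALSE]   # far first (painter's order)
    for (i in seq_len(nrow(bx))) {
      px <- box_pixels(depth_frame(d), with(bx[i, ], c(x, y, x + w, y + h)))
      if (!length(px$u)) next
      np <- length(px$u)
      z <- bx$z_m[i] * cam$depth_scale
      vals <- if (cfg$depth_noise_frac > 0)
        z * (1 + rng$norm(np, sd = cfg$depth_noise_frac)) else rep(z, np)
      if (cfg$bg_contamination_frac > 0) {
        nbg <- round(cfg$bg_contamination_frac * np)
        if (nbg > 0) {
          which_bg <- rng$int(nbg, np)
          vals[which_bg] <- cfg$background_depth_m * cam$depth_scale
        }
      }
      d[cbind(px$v + 1L, px$u + 1L)] <- round(vals)
    }
  }
  depth_frame(d)
}

in_window <- function(id, frame, win) {
  any(vapply(win, function(w)
    id %in% w$ids && frame >= w$from && frame <= w$to, logical(1)))
}

#' Generate detector output for one scene frame
#'
#' Per visible ear: confidence drawn uniformly from `confidence_range`,
#' box center and size perturbed by Gaussian noise with std
#' `kappa (1 - c) true_h_px`; occlusion windows drop the detection or
#' degrade it (confidence forced to the range's low end, noise tripled).
#' False positives appear at `fp_rate` per frame with random boxes and
#' low-end confidence; embeddings are drawn from per-identity unit-norm
#' Gaussian clusters.
#'
#' @inheritParams render_depth_frame
#' @return Detection data.frame (`frame, id, x, y, w, h, conf`, embedding
#'   columns `e1..eD`, and `gt_id` for diagnostics; `id` is -1 as for raw
#'   detector output).
#' @export
generate_detections <- function(gt, frame, cfg = gt$config, rng = NULL) {
  if (is.null(rng)) rng <- local_rng(cfg$seed)$spawn(2000L + frame)
  cam <- cfg$camera
  bx <- gt$boxes[gt$boxes$frame == frame & gt$boxes$visible, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(bx))) {
    id <- bx$id[i]
    mode <- NULL
    if (length(cfg$occlusion_windows)) {
      for (wn in cfg$occlusion_windows)
        if (id %in% wn$ids && frame >= wn$from && frame <= wn$to) mode <- wn$mode
    }
    if (identical(mode, "drop")) next
    cc <- rng$unif(1, cfg$confidence_range[1], cfg$confidence_range[2])
    mult <- 1
    if (identical(mode, "degrade")) { cc <- cfg$confidence_range[1]; mult <- 3 }
    sdv <- cfg$kappa * (1 - cc) * bx$h[i] * mult
    nz <- rng$norm(4, sd = sdv)
    w <- max(bx$w[i] + nz[3], 2); h <- max(bx$h[i] + nz[4], 2)
    ctr <- c(bx$x[i] + bx$w[i] / 2 + nz[1], bx$y[i] + bx$h[i] / 2 + nz[2])
    row <- data.frame(frame = frame, id = -1L,
                      x = ctr[1] - w / 2, y = ctr[2] - h / 2, w = w, h = h,
                      conf = cc, gt_id = id)
    if (!is.null(gt$embeddings)) {
      e <- gt$embeddings[id, ] + rng$norm(cfg$embedding_dim,
                                          sd = cfg$embedding_cluster_std)
      e <- e / sqrt(sum(e^2))
      row[paste0("e", seq_len(cfg$embedding_dim))] <- as.list(e)
    }
    out[[length(out) + 1L]] <- row
  }
  if (cfg$fp_rate > 0 && rng$bern(1, min(cfg$fp_rate, 1))) {
    w <- rng$unif(1, 15, 40); h <- rng$unif(1, 30, 90)
    row <- data.frame(frame = frame, id = -1L,
                      x = rng$unif(1, 0, cam$width - w),
                      y = rng$unif(1, 0, cam$height - h),
                      w = w, h = h,
                      conf = cfg$confidence_range[1] + rng$unif(1, 0, 0.05),
                      gt_id = NA_integer_)
    if (!is.null(gt$embeddings)) {
      e <- rng$norm(cfg$embedding_dim); e <- e / sqrt(sum(e^2))
      row[paste0("e", seq_len(cfg$embedding_dim))] <- as.list(e)
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out))
    return(data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0), gt_id = integer(0)))
  do.call(rbind, out)
}

#' Generate detections for every frame of a scene
#'
#' @param gt A [generate_scene()] result.
#' @param cfg The scene's [scene_config()].
#' @return Detection data.frame over all frames.
#' @export
generate_all_detections <- function(gt, cfg = gt$config) {
  do.call(rbind, lapply(seq_len(cfg$frames) - 1L, function(f)
    generate_detections(gt, f, cfg)))
}

#' Write a full simulated sequence to disk
#'
#' Produces `gt.csv` (ground-truth boxes), `gt_heights.csv` (per-ear true
#' heights), `det.txt` (detections, MOT dialect with extra columns), depth
#' frames `depth_%06d.tif`, `camera.yaml` and `scene_config.yaml`
#' (the resolved configuration including the seed).
#'
#' @param cfg A [scene_config()].
#' @param out_dir Output directory (created if missing).
#' @return The scene ground truth, invisibly.
#' @export
simulate_scene <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_scene(cfg)
  dets <- generate_all_detections(gt, cfg)
  write_detections(dets, file.path(out_dir, "det.txt"))
  gtb <- gt$boxes[gt$boxes$visible,
                  c("frame", "id", "x", "y", "w", "h", "height_m", "row")]
  write_mot_csv(gtb, file.path(out_dir, "gt.csv"))
  utils::write.csv(gt$ears[, c("id", "height_m", "row")],
                   file.path(out_dir, "gt_heights.csv"), row.names = FALSE)
  for (f in seq_len(cfg$frames) - 1L) {
    write_depth(render_depth_frame(gt, f, cfg),
                file.path(out_dir, sprintf("depth_%06d.tif", f)))
  }
  write_camera_config(cfg$camera, file.path(out_dir, "camera.yaml"))
  resolved <- cfg; resolved$camera <- NULL
  yaml::write_yaml(c(resolved,
                     list(camera = file.path(out_dir, "camera.yaml"))),
                   file.path(out_dir, "scene_config.yaml"))
  invisible(gt)
}
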