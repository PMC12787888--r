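unit_embedding <- function(theta, dim = 4) {
  e <- rep(0, dim); e[1] <- cos(theta); e[2] <- sin(theta)
  e
}

det_with_embedding <- function(frame, x, y, w, h, conf, e) {
  d <- make_dets(frame, x, y, w, h, conf)
  d[paste0("e", seq_along(e))] <- as.list(e)
  d
}

test_that("gating distance is zero at the prediction and respects confidence", {
  cfg <- tracker_config()
  tr <- cehd:::new_track(1L, c(50, 50, 1, 40), 0.8, NULL, cfg)
  tr$state <- kf_predict(tr$state, cfg$filter)
  at_pred <- tr$state$mean[1:4]
  det0 <- make_dets(0, at_pred[1] - at_pred[3] * at_pred[4] / 2,
                    at_pred[2] - at_pred[4] / 2,
                    at_pred[3] * at_pred[4], at_pred[4], conf = 0.8)
  expect_lt(gating_distance(tr, det0, cfg), 1e-16)

  off <- make_dets(0, at_pred[1] - 15, at_pred[2] - 20, 40, 40, conf = 0.9)
  off_lo <- off; off_lo$conf <- 0.1
  # higher confidence -> smaller R -> larger whitened distance
  expect_gt(gating_distance(tr, off, cfg), gating_distance(tr, off_lo, cfg))
})

test_that("appearance distance takes the gallery minimum of cosine distances", {
  cfg <- tracker_config()
  e <- unit_embedding(0)
  tr <- cehd:::new_track(1L, c(0, 0, 1, 10), 0.8, e, cfg)
  same <- det_with_embedding(0, 0, 0, 10, 10, 0.8, e)
  orth <- det_with_embedding(0, 0, 0, 10, 10, 0.8, unit_embedding(pi / 2))
  expect_equal(appearance_distance(tr, same, cfg), 0, tolerance = 1e-12)
  expect_equal(appearance_distance(tr, orth, cfg), 1, tolerance = 1e-12)
  tr$gallery <- list(e, -e)
  expect_equal(appearance_distance(tr, same, cfg), 0, tolerance = 1e-12)
  no_emb <- make_dets(0, 0, 0, 10, 10)
  expect_true(is.na(appearance_distance(tr, no_emb, cfg)))
})

test_that("association matches co-located pairs and leaves the rest unmatched", {
  cfg <- tracker_config(n_init = 1)
  tr <- cehd:::new_track(1L, c(50, 50, 1, 40), 0.8, unit_embedding(0), cfg)
  tr$status <- "confirmed"
  tr$state <- kf_predict(tr$state, cfg$filter)
  tr$time_since_update <- 1L
  det <- det_with_embedding(1, 30, 30, 40, 40, 0.8, unit_embedding(0))
  res <- associate(list(tr), det, cfg)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches[1, ], c(1L, 1L))

  res2 <- associate(list(tr), det[0, ], cfg)
  expect_equal(res2$unmatched_tracks, 1L)
  expect_equal(nrow(res2$matches), 0L)
})

test_that("crossing targets keep their identities through embeddings", {
  cfg <- tracker_config()
  # two targets crossing linearly over 30 frames, distinctive embeddings
  dets <- do.call(rbind, lapply(0:29, function(f) {
    rbind(det_with_embedding(f, 20 + 4 * f, 50, 20, 40, 0.9, unit_embedding(0)),
          det_with_embedding(f, 140 - 4 * f, 50, 20, 40, 0.9, unit_embedding(pi / 2)))
  }))
  tr <- run_tracker(dets, 30L, cfg)
  # the left-starting target keeps one id for its whole trajectory
  first <- tr[tr$frame == 0, ]
  left_id <- first$track_id[which.min(first$x)]
  left_tracks <- tr[tr$track_id == left_id, ]
  expect_equal(nrow(left_tracks), 30L)
  # it ends on the right side (x increased throughout, no swap)
  expect_gt(left_tracks$x[left_tracks$frame == 29], 100)
  # no double assignments anywhere
  expect_false(any(duplicated(tr[, c("frame", "track_id")])))
})

test_that("track lifecycle confirms, coasts and deletes", {
  cfg <- tracker_config(n_init = 3, max_age = 5)
  tk <- new_tracker(cfg)
  # empty first frame: no tracks
  out <- track_frame(tk, make_dets(0, 1, 1, 1, 1)[0, ], 0)
  expect_length(out$tracker$tracks, 0L)
  tk <- out$tracker
  for (f in 1:10) {
    out <- track_frame(tk, make_dets(f, 50 + f, 50, 20, 40, conf = 0.9), f)
    tk <- out$tracker
  }
  expect_length(tk$tracks, 1L)
  expect_equal(tk$tracks[[1]]$status, "confirmed")
  # absence beyond max_age deletes the track
  for (f in 11:17) {
    out <- track_frame(tk, make_dets(f, 0, 0, 1, 1)[0, ], f)
    tk <- out$tracker
  }
  expect_length(tk$tracks, 0L)
})

test_that("a single clean target yields one confirmed track and no switches", {
  cfg <- scene_config(n_ears_target_row = 1, n_ears_far_row = 0, frames = 10,
                      kappa = 0, fp_rate = 0,
                      camera_speed_m_per_frame = 0.004, seed = 4)
  gt <- generate_scene(cfg)
  dets <- generate_all_detections(gt, cfg)
  tr <- run_tracker(dets, 10L)
  expect_equal(length(unique(tr$track_id)), 1L)
  gtb <- gt$boxes[gt$boxes$visible, c("frame", "id", "x", "y", "w", "h")]
  m <- mot_metrics(tr, gtb)
  expect_equal(m$id_switches, 0L)
})

test_that("tracker output is deterministic for identical input", {
  cfg <- scene_config(n_ears_target_row = 4, frames = 25, seed = 12)
  gt <- generate_scene(cfg)
  dets <- generate_all_detections(gt, cfg)
  expect_identical(run_tracker(dets, 25L), run_tracker(dets, 25L))
})
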