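test_that("scene generation is deterministic and respects configuration", {
  cfg <- scene_config(n_ears_target_row = 20, n_ears_far_row = 3,
                      frames = 15, seed = 10)
  gt1 <- generate_scene(cfg)
  gt2 <- generate_scene(cfg)
  expect_identical(gt1$ears, gt2$ears)
  expect_identical(gt1$boxes, gt2$boxes)
  expect_equal(sum(gt1$ears$row == "target"), 20L)
  expect_equal(sum(gt1$ears$row == "far"), 3L)
  expect_true(all(gt1$ears$height_m >= 0.8 & gt1$ears$height_m <= 1.5))
})

test_that("noise-free depth rendering writes exact box depths in painter order", {
  cfg <- scene_config(n_ears_target_row = 3, n_ears_far_row = 3, frames = 20,
                      depth_noise_frac = 0, bg_contamination_frac = 0, seed = 6)
  gt <- generate_scene(cfg)
  f <- gt$boxes$frame[gt$boxes$visible][1]
  dep <- render_depth_frame(gt, f, cfg)
  bx <- gt$boxes[gt$boxes$frame == f & gt$boxes$visible, ]
  for (i in seq_len(nrow(bx))) {
    med <- box_depth(dep, with(bx[i, ], c(x, y, x + w, y + h)),
                     depth_filter_config(shrink_fraction = 0.5), cfg$camera)
    expect_equal(med, bx$z_m[i], tolerance = 2e-3)
  }
  # far-row boxes carry larger median depth than target-row boxes
  if (any(bx$row == "far") && any(bx$row == "target"))
    expect_gt(min(bx$z_m[bx$row == "far"]), max(bx$z_m[bx$row == "target"]))
})

test_that("perfect confidence yields exact detection boxes", {
  cfg <- scene_config(n_ears_target_row = 4, frames = 10, kappa = 0.3,
                      confidence_range = c(1, 1), fp_rate = 0, seed = 5)
  gt <- generate_scene(cfg)
  for (f in 0:9) {
    dets <- generate_detections(gt, f, cfg)
    bx <- gt$boxes[gt$boxes$frame == f & gt$boxes$visible, ]
    expect_equal(nrow(dets), nrow(bx))
    if (nrow(dets)) {
      m <- match(dets$gt_id, bx$id)
      expect_equal(dets$x, bx$x[m], tolerance = 1e-9)
      expect_equal(dets$h, bx$h[m], tolerance = 1e-9)
    }
  }
})

test_that("detection noise follows the stated confidence-dependent law", {
  # pin the box height via a single far ear and fixed confidence
  cfg <- scene_config(n_ears_target_row = 1, frames = 1, kappa = 0.2,
                      confidence_range = c(0.5, 0.5), fp_rate = 0, seed = 1)
  gt <- generate_scene(cfg)
  bx <- gt$boxes[gt$boxes$visible, ][1, ]
  draws <- vapply(1:10000, function(k) {
    d <- generate_detections(gt, 0, cfg, rng = local_rng(k))
    d$x[1] + d$w[1] / 2
  }, numeric(1))
  expected_sd <- 0.2 * 0.5 * bx$h
  expect_equal(sd(draws), expected_sd, tolerance = 0.03)
})

test_that("embeddings cluster by identity", {
  cfg <- scene_config(n_ears_target_row = 6, frames = 40,
                      embedding_cluster_std = 0.1, seed = 13)
  gt <- generate_scene(cfg)
  dets <- generate_all_detections(gt, cfg)
  ecols <- grep("^e[0-9]+$", names(dets))
  E <- as.matrix(dets[, ecols])
  D <- 1 - E %*% t(E)
  same <- outer(dets$gt_id, dets$gt_id, "==")
  diag(same) <- NA
  intra <- mean(D[same & upper.tri(D)], na.rm = TRUE)
  inter <- mean(D[!same & upper.tri(D)], na.rm = TRUE)
  expect_lt(intra, inter)
})

test_that("simulated sequences roundtrip through the on-disk formats", {
  dir <- tempfile("scene")
  cfg <- scene_config(n_ears_target_row = 2, n_ears_far_row = 1, frames = 4,
                      seed = 3)
  gt <- simulate_scene(cfg, dir)
  expect_true(file.exists(file.path(dir, "det.txt")))
  expect_true(file.exists(file.path(dir, "gt.csv")))
  expect_true(file.exists(file.path(dir, "camera.yaml")))
  expect_true(file.exists(file.path(dir, sprintf("depth_%06d.tif", 3))))
  dets <- read_detections(file.path(dir, "det.txt"))
  expect_true(all(dets$frame >= 0 & dets$frame < 4))
  dep <- read_depth(file.path(dir, "depth_000000.tif"))
  expect_identical(dep$data, render_depth_frame(gt, 0, cfg)$data)
  cam <- read_camera_config(file.path(dir, "camera.yaml"))
  expect_equal(cam$mount_height, 1.8)
  expect_equal(cam$pitch, pi / 4)
  unlink(dir, recursive = TRUE)
})
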