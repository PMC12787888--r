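test_that("distribution statistics summarize softmaxed side distributions", {
  cfg <- quality_config(k = 4, n_bins = 16)
  stat <- distribution_stat(matrix(0, 4, 16), cfg)
  expect_length(stat, 4 * 5)
  expect_true(all(abs(stat - 1 / 16) < 1e-12))

  # saturated side: one dominant logit
  lg <- matrix(0, 4, 16); lg[1, 3] <- 20
  cfg1 <- quality_config(k = 1, n_bins = 16)
  s <- distribution_stat(lg, cfg1)
  expect_equal(s[1], 1, tolerance = 1e-6)   # top-1 of side 1
  expect_equal(s[2], 1, tolerance = 1e-6)   # its mean

  # shift invariance per side
  lg2 <- matrix(rnorm(64), 4, 16)
  lg3 <- lg2 + 7.5
  expect_equal(distribution_stat(lg2, cfg), distribution_stat(lg3, cfg),
               tolerance = 1e-12)

  expect_error(distribution_stat(matrix(0, 4, 3), quality_config(k = 4, n_bins = 4)),
               "k exceeds")
})

test_that("quality score is the deterministic head output", {
  cfg <- quality_config(k = 4, n_bins = 16)
  stat <- distribution_stat(matrix(0, 4, 16), cfg)
  # zero single-layer head
  cfg$mlp_weights <- list(list(W = matrix(0, 1, 20), b = 0))
  expect_equal(quality_score(stat, cfg), 0)
  # linear head equals the hand dot product
  w <- seq(-1, 1, length.out = 20)
  cfg$mlp_weights <- list(list(W = matrix(w, 1, 20), b = 0.3))
  expect_equal(quality_score(stat, cfg), sum(w * stat) + 0.3, tolerance = 1e-12)
  expect_identical(quality_score(stat, cfg), quality_score(stat, cfg))
  # dimension mismatch
  cfg$mlp_weights <- list(list(W = matrix(0, 1, 7), b = 0))
  expect_error(quality_score(stat, cfg), "expects input of length")
  # two-layer head with ReLU
  cfgh <- quality_config(k = 4, n_bins = 16,
                         mlp_weights = make_quality_mlp(20, hidden = 8, seed = 3))
  q1 <- quality_score(stat, cfgh)
  expect_true(is.finite(q1))
  expect_identical(q1, quality_score(stat, cfgh))
})

test_that("score fusion follows the additive and multiplicative forms", {
  expect_equal(lqe_score(0.5, 0.2), 0.7)
  expect_equal(lqe_score(0.4, 0), 0.4)
  expect_equal(lqe_score(lqe_score(0.5, 0.1), 0.2), lqe_score(0.5, 0.3))

  expect_equal(occlusion_factor(0), 0.5)
  expect_equal(occlusion_factor(0.75), 0.6792, tolerance = 1e-4)
  s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(occlusion_factor(s)) > 0))

  expect_equal(aqe_score(0.5, 0.2, 0.6, "additive"), 0.62, tolerance = 1e-12)
  expect_equal(aqe_score(0.5, 0, 0.6, "multiplicative"), 0.5 * 0.5 * 0.6,
               tolerance = 1e-12)
  expect_equal(aqe_score(0, 3, 0.7, "multiplicative"), 0)
  expect_error(aqe_score(0.5, 0.2, 0.6, "bogus"))
})

test_that("the output gate is inclusive at the threshold", {
  cfg <- quality_config(gate_threshold = 0.75)
  expect_false(aqe_gate(0.74, cfg))
  expect_true(aqe_gate(0.75, cfg))
  expect_true(all(aqe_gate(c(0, 0.3, 1), quality_config(gate_threshold = 0))))
})

test_that("multiplicative fusion suppresses low-confidence high-quality boxes", {
  O <- occlusion_factor(0.3)
  for (Q in c(-2, 0, 1, 5, 50)) {
    sp <- aqe_score(0.3, Q, O, "multiplicative")
    expect_lte(sp, 0.3)
    expect_false(aqe_gate(sp, quality_config()))
  }
  # multiplicative fused score never exceeds S for any probability input
  rng <- local_rng(17)
  S <- rng$unif(200); Q <- rng$norm(200, sd = 3)
  sp <- aqe_score(S, Q, occlusion_factor(S), "multiplicative")
  expect_true(all(sp <= S + 1e-12))
  # additive with nonnegative Q never decreases the score
  Qp <- abs(Q)
  expect_true(all(aqe_score(S, Qp, occlusion_factor(S), "additive") >= S))

  # a high-confidence, high-quality box passes the gate under additive
  # fusion, and under multiplicative fusion fed the score as its own
  # occlusion weight (logit-input mode, O = S)
  expect_true(aqe_gate(aqe_score(0.95, 3, occlusion_factor(0.95), "additive"),
                       quality_config()))
  expect_true(aqe_gate(0.95 * occlusion_factor(3) * 0.95, quality_config()))
})

test_that("apply_aqe gates detections or passes through without inputs", {
  dets <- make_dets(0, x = c(0, 50), y = c(0, 0), w = 20, h = 40,
                    conf = c(0.3, 0.95))
  out <- apply_aqe(dets, quality_config())
  expect_identical(nrow(out), 2L)
  expect_true(attr(out, "aqe_skipped"))

  # precomputed quality with additive fusion: only the confident box passes
  dets$quality_q <- c(5, 3)
  cfg <- quality_config(fusion_mode = "additive")
  out2 <- apply_aqe(dets, cfg)
  expect_false(attr(out2, "aqe_skipped"))
  expect_true(all(out2$score_fused >= 0.75))

  # regression-logit route with a linear head
  cfg3 <- quality_config(k = 2, n_bins = 4, fusion_mode = "additive",
                         mlp_weights = list(list(W = matrix(1, 1, 12), b = 0)))
  dets3 <- make_dets(0, x = 0, y = 0, w = 20, h = 40, conf = 0.5)
  dets3[paste0("reg", 1:16)] <- as.list(rep(0, 16))
  out3 <- apply_aqe(dets3, cfg3)
  stat <- distribution_stat(rep(0, 16), cfg3)
  expect_equal(out3$quality_q, sum(stat))
})
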