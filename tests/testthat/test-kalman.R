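test_that("track initiation sets state and a valid covariance", {
  st <- kf_initiate(c(10, 20, 0.5, 40))
  expect_equal(st$mean, c(10, 20, 0.5, 40, 0, 0, 0, 0))
  expect_equal(st$smoothed, c(10, 20))
  expect_equal(st$cov, t(st$cov))
  expect_true(all(eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_identical(st, kf_initiate(c(10, 20, 0.5, 40)))
  expect_error(kf_initiate(c(0, 0, 0.5, -1)), "invalid detection")
  expect_error(kf_initiate(c(0, 0, 0, 10)), "invalid detection")
})

test_that("prediction propagates at constant velocity and matches dense algebra", {
  p <- filter_params()
  st <- kf_initiate(c(5, 6, 1, 10), p)
  pred <- kf_predict(st, p)
  expect_equal(pred$mean[1:4], st$mean[1:4])   # zero velocity: statics fixed

  st$mean <- c(0, 0, 1, 10, 1, 0, 0, 0)
  expect_equal(kf_predict(st, p)$mean, c(1, 0, 1, 10, 1, 0, 0, 0))

  rng <- local_rng(33)
  for (i in 1:100) {
    A <- matrix(rng$norm(64), 8, 8)
    P <- A %*% t(A) + diag(8) * 0.1
    st$cov <- P
    st$mean <- c(rng$norm(2, sd = 50), runif_h <- rng$unif(1, 0.3, 2),
                 rng$unif(1, 20, 120), rng$norm(4))
    pred <- kf_predict(st, p)
    Q <- oracle_process_noise(max(st$mean[4], 1))
    expect_equal(pred$cov, p$F %*% P %*% t(p$F) + Q, tolerance = 1e-12)
    expect_gte(sum(diag(pred$cov)), sum(diag(p$F %*% P %*% t(p$F))) - 1e-12)
  }
})

test_that("adaptive noise follows the confidence-weighted law", {
  p <- filter_params(w = 0.05, eps = 0.01)
  R <- adaptive_noise(1, 100, p)
  expect_equal(sqrt(diag(R)), c(0.05, 1.0, 0.05, 0.05), tolerance = 1e-12)
  R0 <- adaptive_noise(0, 100, p)
  expect_equal(sqrt(R0[1, 1]), 5.0)
  expect_equal(sqrt(diag(R0)), c(5, 5, 0.1, 5), tolerance = 1e-12)
  # each sigma non-increasing in confidence
  cs <- c(0, 0.25, 0.5, 0.75, 1)
  sig <- t(vapply(cs, function(cc) sqrt(diag(adaptive_noise(cc, 100, p))),
                  numeric(4)))
  for (j in 1:4) expect_true(all(diff(sig[, j]) <= 1e-12))
  expect_warning(adaptive_noise(1.2, 100, p), "clipped")
})

test_that("updates behave at the gain limits and match dense algebra", {
  p <- filter_params()
  st <- kf_initiate(c(50, 60, 1, 30), p)
  st <- kf_predict(st, p)
  z <- drop(p$H %*% st$mean)
  up <- kf_update(st, z, diag(4), p)
  expect_equal(up$mean, st$mean, tolerance = 1e-12)   # zero innovation

  up_inf <- kf_update(st, z + c(10, -5, 0.2, 8), diag(4) * 1e12, p)
  expect_equal(up_inf$mean, st$mean, tolerance = 1e-6) # zero-gain limit

  # H P H^T = I, R = I: gain exactly 0.5 on observed dims
  st2 <- st
  st2$cov <- diag(c(1, 1, 1, 1, 2, 2, 2, 2))
  innov <- c(2, -2, 0.4, 4)
  up2 <- kf_update(st2, drop(p$H %*% st2$mean) + innov, diag(4), p)
  expect_equal(up2$mean[1:4] - st2$mean[1:4], innov / 2, tolerance = 1e-12)

  rng <- local_rng(44)
  for (i in 1:50) {
    A <- matrix(rng$norm(64), 8, 8)
    st$cov <- A %*% t(A) + diag(8) * 0.1
    R <- diag(rng$unif(4, 0.1, 3)^2)
    z <- drop(p$H %*% st$mean) + rng$norm(4)
    up <- kf_update(st, z, R, p)
    S <- p$H %*% st$cov %*% t(p$H) + R
    K <- st$cov %*% t(p$H) %*% solve(S)
    expect_equal(up$mean, st$mean + drop(K %*% (z - p$H %*% st$mean)),
                 tolerance = 1e-10)
    expect_equal(up$cov, (diag(8) - K %*% p$H) %*% st$cov, tolerance = 1e-10)
    expect_lte(sum(diag(p$H %*% up$cov %*% t(p$H))), sum(diag(S - R)) + 1e-9)
  }
})

test_that("with constant R the filter equals a textbook Kalman over 200 cycles", {
  p <- filter_params()
  rng <- local_rng(7)
  st <- kf_initiate(c(100, 80, 0.6, 50), p)
  mean_o <- st$mean; cov_o <- st$cov
  R <- diag(c(2, 2, 0.05, 2)^2)
  for (k in 1:200) {
    z <- c(100, 80, 0.6, 50) + rng$norm(4, sd = c(3, 3, 0.05, 3))
    h_now <- max(st$mean[4], 1)
    st <- kf_predict(st, p)
    st <- kf_update(st, z, R, p)
    o <- textbook_kalman_step(mean_o, cov_o, p$F,
                              oracle_process_noise(max(mean_o[4], 1)),
                              p$H, R, z)
    mean_o <- o$mean; cov_o <- o$cov
    expect_equal(st$mean, mean_o, tolerance = 1e-10)
    expect_equal(st$cov, cov_o, tolerance = 1e-10)
  }
})

test_that("high confidence pulls the update closer to the observation", {
  p <- filter_params()
  st <- kf_initiate(c(0, 0, 1, 100), p)
  st <- kf_predict(st, p)
  z <- c(20, 15, 1.1, 110)
  up1 <- kf_update(st, z, adaptive_noise(1, 100, p), p)
  up0 <- kf_update(st, z, adaptive_noise(0, 100, p), p)
  d1 <- sqrt(sum((up1$mean[1:4] - z)^2))
  d0 <- sqrt(sum((up0$mean[1:4] - z)^2))
  expect_lt(d1, d0)
})

test_that("center smoothing interpolates exactly", {
  expect_identical(smooth_center(c(1, 2), c(3, 8), 0), c(3, 8))
  expect_identical(smooth_center(c(1, 2), c(3, 8), 1), c(1, 2))
  expect_equal(smooth_center(c(2, 2), c(4, 4), 0.5), c(3, 3))
})

test_that("smoothing reduces center variance on a static noisy track", {
  for (alpha in c(0.3, 0.5, 0.7)) {
    wins <- vapply(1:50, function(sd) {
      rng <- local_rng(sd)
      p <- filter_params(alpha = alpha)
      st <- kf_initiate(c(100, 100, 1, 50), p)
      raw <- sm <- matrix(NA_real_, 80, 2)
      for (k in 1:80) {
        z <- c(100, 100, 1, 50) + rng$norm(4, sd = c(4, 4, 0.02, 2))
        st <- kf_step(st, z, conf = 0.6, p)
        raw[k, ] <- st$mean[1:2]
        sm[k, ] <- st$smoothed
      }
      sum(apply(sm[20:80, ], 2, var)) < sum(apply(raw[20:80, ], 2, var))
    }, logical(1))
    expect_gte(mean(wins), 0.9)
  }
})

test_that("covariance stays symmetric positive definite over 1000 cycles", {
  p <- filter_params()
  rng <- local_rng(99)
  st <- kf_initiate(c(50, 50, 1, 40), p)
  for (k in 1:1000) {
    z <- c(50 + rng$norm(1, sd = 3), 50 + rng$norm(1, sd = 3),
           1 + rng$norm(1, sd = 0.02), 40 + rng$norm(1, sd = 2))
    st <- kf_step(st, z, conf = rng$unif(1, 0.2, 1), p)
  }
  expect_equal(st$cov, t(st$cov))
  expect_gt(min(eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values), 1e-9)
})

test_that("a missed detection predicts only and coasts the smoothed center", {
  p <- filter_params()
  st <- kf_initiate(c(10, 10, 1, 20), p)
  st$mean[5:6] <- c(2, -1)
  pred <- kf_predict(st, p)
  stepped <- kf_step(st, NULL, params = p)
  expect_equal(stepped$mean, pred$mean)
  expect_equal(stepped$smoothed, st$smoothed + c(2, -1))
  # determinism
  expect_identical(kf_step(st, c(12, 9, 1, 20), 0.8, p),
                   kf_step(st, c(12, 9, 1, 20), 0.8, p))
})
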