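#' Parameters of the independent-dimension adaptive Kalman filter
#'
#' A constant-velocity filter over the 8-dimensional track state
#' (x, y, a, h, and their per-frame velocities), where (x, y) is the box
#' center in pixels, `a` the width/height aspect ratio and `h` the box
#' height in pixels. Observation noise is re-derived every update from the
#' detection confidence, per dimension (see [adaptive_noise()]).
#'
#' @param w Position normalization weight: observation/initialization
#'   standard deviations scale as `w * h` (default 0.05 = 1/20, the
#'   standard DeepSORT scaling).
#' @param eps Noise lower bound, keeps observation noise positive as
#'   confidence approaches 1 (default 0.01).
#' @param alpha Exponential smoothing coefficient for the reported center,
#'   in [0, 1]; larger is more stable (default 0.7).
#' @param q_pos,q_vel Process-noise std weights per frame as fractions of
#'   box height (defaults 1/20 and 1/160).
#' @param coef Per-dimension confidence weights in `max(1 - coef * c, eps)`
#'   for (x, y, a, h); defaults `c(1, 0.8, 0.5, 1)`.
#' @return An object of class `filter_params` carrying the 8x8 transition
#'   matrix `F`, 4x8 observation matrix `H`, and the control matrix `B`
#'   with input `u` (identically zero: tracking has no control input).
#' @export
filter_params <- function(w = 0.05, eps = 0.01, alpha = 0.7,
                          q_pos = 1 / 20, q_vel = 1 / 160,
                          coef = c(1, 0.8, 0.5, 1)) {
  stopifnot(w > 0, eps > 0, alpha >= 0, alpha <= 1, length(coef) == 4)
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1            # x += vx etc., dt = 1 frame
  H <- cbind(diag(4), matrix(0, 4, 4))
  structure(list(F = F, H = H, B = matrix(0, 8, 8), u = numeric(8),
                 w = w, eps = eps, alpha = alpha,
                 q_pos = q_pos, q_vel = q_vel, coef = coef),
            class = "filter_params")
}

# process noise covariance, std proportional to current box height
process_noise <- function(h, params) {
  s <- c(params$q_pos * h, params$q_pos * h, 1e-2, params$q_pos * h,
         params$q_vel * h, params$q_vel * h, 1e-5, params$q_vel * h)
  diag(s^2)
}

#' Initiate a track state from a detection
#'
#' Zero initial velocity; diagonal covariance with position std `2 w h`,
#' velocity std `10 w h` and aspect std 0.01.
#'
#' @param z Observation 4-vector `c(x, y, a, h)` (center, aspect, height).
#' @param params A [filter_params()].
#' @return A `track_state` list: `mean` (8-vector), `cov` (8x8),
#'   `smoothed` (smoothed center, initialized at the observation).
#' @export
kf_initiate <- function(z, params = filter_params()) {
  z <- as.numeric(z)
  if (z[4] <= 0 || z[3] <= 0) stop("invalid detection: non-positive h or a")
  s <- c(rep(2 * params$w * z[4], 2), 1e-2, 2 * params$w * z[4],
         rep(10 * params$w * z[4], 2), 1e-5, 10 * params$w * z[4])
  structure(list(mean = c(z, rep(0, 4)), cov = diag(s^2),
                 smoothed = z[1:2]),
            class = "track_state")
}

#' Predict the next-frame state
#'
#' Constant-velocity propagation: `mean' = F mean` (the control term is
#' identically zero), `cov' = F cov F^T + Q` with process noise scaled by
#' the current height estimate.
#'
#' @param state A `track_state`.
#' @param params A [filter_params()].
#' @return The predicted `track_state`.
#' @export
kf_predict <- function(state, params = filter_params()) {
  Q <- process_noise(max(state$mean[4], 1), params)
  state$mean <- drop(params$F %*% state$mean + params$B %*% params$u)
  state$cov <- symmetrize(params$F %*% state$cov %*% t(params$F) + Q)
  state
}

#' Confidence-adaptive observation noise
#'
#' Observation noise standard deviations shrink as detection confidence
#' rises, independently per dimension:
#' `sx = max(1 - c, eps) w h`, `sy = max(1 - 0.8 c, eps) w h`,
#' `sa = max(1 - 0.5 c, eps) 0.1`, `sh = max(1 - c, eps) w h`,
#' where `h` is the previous-frame height estimate. The filter thus leans
#' on observations when detection is reliable and on the motion prediction
#' when it is not.
#'
#' @param c Detection confidence in [0, 1]; values outside are clipped
#'   with a warning (fused scores occasionally exceed 1).
#' @param h_prev Previous-frame (pre-update) height estimate, pixels (> 0).
#' @param params A [filter_params()].
#' @return 4x4 diagonal observation-noise covariance R_t.
#' @export
adaptive_noise <- function(c, h_prev, params = filter_params()) {
  stopifnot(h_prev > 0)
  if (c < 0 || c > 1) {
    warning("confidence ", signif(c, 4), " outside [0,1]; clipped")
    c <- min(max(c, 0), 1)
  }
  f <- pmax(1 - params$coef * c, params$eps)
  s <- c(f[1] * params$w * h_prev, f[2] * params$w * h_prev,
         f[3] * 0.1, f[4] * params$w * h_prev)
  diag(s^2)
}

#' Fixed observation noise of the conventional filter
#'
#' The non-adaptive baseline: position/height std `w h`, aspect std 0.1,
#' independent of detection confidence.
#'
#' @inheritParams adaptive_noise
#' @return 4x4 diagonal observation-noise covariance.
#' @export
fixed_noise <- function(h_prev, params = filter_params()) {
  s <- c(params$w * h_prev, params$w * h_prev, 0.1, params$w * h_prev)
  diag(s^2)
}

#' Measurement update
#'
#' Standard Kalman correction with the supplied observation-noise
#' covariance: `K = P H^T (H P H^T + R)^-1`, `mean' = mean + K (z - H mean)`,
#' `cov' = (I - K H) P` (symmetrized).
#'
#' @param state A predicted `track_state`.
#' @param z Observation 4-vector `c(x, y, a, h)`.
#' @param R 4x4 observation-noise covariance (SPD).
#' @param params A [filter_params()].
#' @return The posterior `track_state`.
#' @export
kf_update <- function(state, z, R, params = filter_params()) {
  H <- params$H
  S <- H %*% state$cov %*% t(H) + R
  K <- tryCatch(t(solve(S, H %*% state$cov)),
                error = function(e) stop("singular innovation covariance; state mean = ",
                                         paste(signif(state$mean, 4), collapse = " ")))
  innov <- as.numeric(z) - drop(H %*% state$mean)
  state$mean <- state$mean + drop(K %*% innov)
  state$cov <- symmetrize((diag(8) - K %*% H) %*% state$cov)
  state
}

symmetrize <- function(M) (M + t(M)) / 2

#' Exponentially smooth a reported center
#'
#' `s_t = alpha * s_prev + (1 - alpha) * updated`, applied to x and y
#' independently. `alpha = 0` returns the update unchanged, `alpha = 1`
#' freezes the previous value.
#'
#' @param prev_smoothed Previous smoothed center `c(x, y)`.
#' @param updated Posterior center `c(x, y)`.
#' @param alpha Smoothing coefficient in [0, 1].
#' @return Smoothed center `c(x, y)`.
#' @export
smooth_center <- function(prev_smoothed, updated, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * prev_smoothed + (1 - alpha) * updated
}

#' One filter step: predict, adaptively weight, update, smooth
#'
#' Composes the full per-frame cycle. With an observation, the adaptive
#' noise uses the pre-update height estimate; the reported center is then
#' exponentially smoothed. To stay unbiased while the platform (and hence
#' every box) moves at near-constant velocity, the previous smoothed
#' center is propagated by the current velocity estimate before blending:
#' for a static target this is exactly the plain exponential update.
#' Without an observation the state is predicted only and the smoothed
#' center coasts with it.
#'
#' @param state A `track_state`.
#' @param z Observation 4-vector or `NULL` (missed detection).
#' @param conf Detection confidence (required with `z`).
#' @param params A [filter_params()].
#' @param adaptive Use confidence-adaptive noise (default TRUE); FALSE
#'   selects the fixed-noise baseline.
#' @param smooth Apply center smoothing (default TRUE).
#' @return The stepped `track_state`.
#' @export
kf_step <- function(state, z = NULL, conf = NULL, params = filter_params(),
                    adaptive = TRUE, smooth = TRUE) {
  h_prev <- state$mean[4]
  state <- kf_predict(state, params)
  if (is.null(z)) {
    state$smoothed <- state$smoothed + state$mean[5:6]
    return(state)
  }
  R <- if (adaptive) adaptive_noise(conf, max(h_prev, 1), params)
       else fixed_noise(max(h_prev, 1), params)
  state <- kf_update(state, z, R, params)
  if (smooth) {
    carried <- state$smoothed + state$mean[5:6]
    state$smoothed <- smooth_center(carried, state$mean[1:2], params$alpha)
  } else {
    state$smoothed <- state$mean[1:2]
  }
  state
}
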