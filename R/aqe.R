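#' Quality-estimation configuration
#'
#' Settings for localization-quality scoring of detector boxes and the
#' occlusion-aware fusion of quality with classification confidence.
#'
#' @param k Top-k probabilities summarized per box side (default 4).
#' @param n_bins Regression bins per side in the discretized corner
#'   distribution (default 16).
#' @param mlp_weights Injectable weights of the quality head, a list of
#'   layers, each `list(W, b)` (`W`: out x in matrix). ReLU between layers,
#'   linear output. `NULL` disables quality scoring.
#' @param fusion_mode `"multiplicative"` (default, the converged-model
#'   behavior: S' = S * sigmoid(Q) * O) or `"additive"` (S' = S + Q * O).
#' @param gate_threshold Final-score output gate (default 0.75, inclusive).
#' @param clip Clip fused scores into [0, 1] (default FALSE).
#' @param logit_input If TRUE the occlusion factor is computed from a
#'   pre-sigmoid classification logit rather than the probability-valued
#'   score (default FALSE).
#' @return An object of class `quality_config`.
#' @export
quality_config <- function(k = 4L, n_bins = 16L, mlp_weights = NULL,
                           fusion_mode = c("multiplicative", "additive"),
                           gate_threshold = 0.75, clip = FALSE,
                           logit_input = FALSE) {
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(k >= 1, n_bins >= 2, k <= n_bins,
            gate_threshold >= 0, gate_threshold <= 1)
  structure(list(k = as.integer(k), n_bins = as.integer(n_bins),
                 mlp_weights = mlp_weights, fusion_mode = fusion_mode,
                 gate_threshold = gate_threshold, clip = clip,
                 logit_input = logit_input),
            class = "quality_config")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Distribution statistics of a box regression distribution
#'
#' Each of the four box sides carries a discretized regression distribution
#' (`n_bins` logits). Per side, logits are softmax-normalized and the top-k
#' probabilities plus their mean form the statistic; the four side blocks
#' are concatenated, giving a vector of length `4 * (k + 1)`.
#'
#' @param logits A 4 x n_bins matrix of regression logits (rows = sides),
#'   or a length-`4 * n_bins` vector filled row-wise.
#' @param cfg A [quality_config()] supplying `k` and `n_bins`.
#' @return Numeric statistic vector of length `4 * (k + 1)`; entries lie in
#'   [0, 1] and each side's top-k block is sorted descending.
#' @export
distribution_stat <- function(logits, cfg = quality_config()) {
  if (is.null(dim(logits)))
    logits <- matrix(logits, nrow = 4, byrow = TRUE)
  stopifnot(nrow(logits) == 4L)
  if (cfg$k > ncol(logits)) stop("k exceeds number of regression bins")
  if (any(!is.finite(logits))) stop("non-finite regression logits")
  out <- lapply(seq_len(4), function(s) {
    p <- softmax(logits[s, ])
    top <- sort(p, decreasing = TRUE)[seq_len(cfg$k)]
    c(top, mean(top))
  })
  unlist(out, use.names = FALSE)
}

#' Quality score from distribution statistics
#'
#' Deterministic forward pass of the quality head: stacked affine layers
#' with ReLU activations, linear last layer, scalar output.
#'
#' @param stat Statistic vector from [distribution_stat()].
#' @param cfg A [quality_config()] with `mlp_weights` set.
#' @return Scalar quality score Q.
#' @export
quality_score <- function(stat, cfg) {
  w <- cfg$mlp_weights
  if (is.null(w)) stop("quality_config has no mlp_weights")
  x <- as.numeric(stat)
  for (i in seq_along(w)) {
    W <- w[[i]]$W; b <- w[[i]]$b
    if (ncol(W) != length(x))
      stop(sprintf("layer %d expects input of length %d, got %d",
                   i, ncol(W), length(x)))
    x <- drop(W %*% x + b)
    if (i < length(w)) x <- pmax(x, 0)
  }
  if (length(x) != 1L) stop("quality head must end in a scalar output")
  as.numeric(x)
}

#' Seeded random quality-head weights
#'
#' One hidden layer (ReLU) of the given width with small Gaussian weights;
#' used to exercise the quality path without shipping a trained head.
#'
#' @param input_dim Statistic length (`4 * (k + 1)`).
#' @param hidden Hidden width (default 64).
#' @param seed RNG seed.
#' @return Weight list accepted by [quality_config()].
#' @export
make_quality_mlp <- function(input_dim, hidden = 64L, seed = 1L) {
  rng <- local_rng(seed)
  list(list(W = matrix(rng$norm(hidden * input_dim, sd = 0.3), hidden, input_dim),
            b = rng$norm(hidden, sd = 0.05)),
       list(W = matrix(rng$norm(hidden, sd = 0.3), 1, hidden),
            b = rng$norm(1, sd = 0.05)))
}

#' Baseline quality-fused score
#'
#' The plain localization-quality refinement adds the quality score to the
#' classification confidence: `S' = S + Q`.
#'
#' @param S Classification score.
#' @param Q Quality score.
#' @return Fused score.
#' @export
lqe_score <- function(S, Q) S + Q

#' Occlusion factor
#'
#' Sigmoid of the classification score: a monotone weight that discounts
#' the quality contribution of boxes whose classification evidence is weak
#' (typically occluded or distant ears).
#'
#' @param S Classification score (or its logit, by configuration).
#' @return `1 / (1 + exp(-S))`.
#' @export
occlusion_factor <- function(S) 1 / (1 + exp(-S))

#' Occlusion-aware fused score
#'
#' Additive fusion `S' = S + Q * O` rewards well-localized boxes; the
#' multiplicative form `S' = S * sigmoid(Q) * O` can only shrink the score,
#' strictly suppressing low-confidence boxes however well localized.
#'
#' @param S Classification score.
#' @param Q Quality score.
#' @param O Occlusion factor from [occlusion_factor()].
#' @param mode `"additive"` or `"multiplicative"`.
#' @return Fused score S'.
#' @export
aqe_score <- function(S, Q, O, mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (mode == "additive") S + Q * O else S * occlusion_factor(Q) * O
}

#' Output gate on fused scores
#'
#' @param S_prime Fused score.
#' @param cfg A [quality_config()].
#' @return Logical: TRUE (emit) iff `S_prime >= gate_threshold` (inclusive).
#' @export
aqe_gate <- function(S_prime, cfg = quality_config()) {
  S_prime >= cfg$gate_threshold
}

#' Apply quality refinement and gating to a detection table
#'
#' For detections carrying regression logits (columns `reg1..regN`,
#' `N = 4 * n_bins`) and a configured quality head, Q is computed from the
#' distribution statistics; detections carrying a precomputed `quality_q`
#' column use it directly. With neither available the stage is a no-op
#' pass-through (scores unchanged, nothing gated) and is flagged as skipped
#' in the returned attributes.
#'
#' @param detections Detection data.frame with a `conf` column.
#' @param cfg A [quality_config()].
#' @return The detections that pass the gate, with columns `quality_q`,
#'   `score_fused` added; attribute `aqe_skipped` is TRUE for pass-through.
#' @export
apply_aqe <- function(detections, cfg = quality_config()) {
  reg_cols <- grep("^reg[0-9]+$", names(detections), value = TRUE)
  has_reg <- length(reg_cols) == 4L * cfg$n_bins && !is.null(cfg$mlp_weights)
  has_q <- "quality_q" %in% names(detections)
  if (!has_reg && !has_q) {
    attr(detections, "aqe_skipped") <- TRUE
    return(detections)
  }
  q <- if (has_reg) {
    vapply(seq_len(nrow(detections)), function(i) {
      lg <- as.numeric(detections[i, reg_cols])
      quality_score(distribution_stat(lg, cfg), cfg)
    }, numeric(1))
  } else detections$quality_q
  S <- detections$conf
  O <- occlusion_factor(if (cfg$logit_input) log(S / (1 - S)) else S)
  Sp <- aqe_score(S, q, O, cfg$fusion_mode)
  if (cfg$clip) Sp <- pmin(pmax(Sp, 0), 1)
  detections$quality_q <- q
  detections$score_fused <- Sp
  out <- detections[aqe_gate(Sp, cfg), , drop = FALSE]
  attr(out, "aqe_skipped") <- FALSE
  out
}
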