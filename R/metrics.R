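#' Match predicted boxes to ground-truth boxes at an IoU threshold
#'
#' Greedy one-to-one matching in descending IoU order: pairs with
#' IoU >= `iou_threshold` become true positives, leftover predictions are
#' false positives, leftover truths false negatives.
#'
#' @param pred,truth Data.frames with `x, y, w, h` (tlwh pixels).
#' @param iou_threshold Matching threshold (default 0.5).
#' @return List of counts `TP, FP, FN, TN` (TN is 0 by convention for
#'   detection).
#' @export
match_boxes <- function(pred, truth, iou_threshold = 0.5) {
  np <- nrow(pred); ng <- nrow(truth)
  if (np == 0L || ng == 0L)
    return(list(TP = 0L, FP = np, FN = ng, TN = 0L))
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) {
    pb <- det_box(pred[i, ])
    for (j in seq_len(ng)) iou[i, j] <- box_iou(pb, det_box(truth[j, ]))
  }
  tp <- 0L
  used_p <- rep(FALSE, np); used_g <- rep(FALSE, ng)
  ord <- order(-iou)
  for (k in ord) {
    if (iou[k] < iou_threshold) break
    i <- (k - 1L) %% np + 1L; j <- (k - 1L) %/% np + 1L
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE; tp <- tp + 1L
  }
  list(TP = tp, FP = np - tp, FN = ng - tp, TN = 0L)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; a zero denominator yields 0
#' with `degenerate = TRUE` so batch reports never break.
#'
#' @param counts List with `TP, FP, FN` (e.g. from [match_boxes()]).
#' @return List `precision, recall, degenerate`.
#' @export
precision_recall <- function(counts) {
  dp <- counts$TP + counts$FP; dr <- counts$TP + counts$FN
  list(precision = if (dp > 0) counts$TP / dp else 0,
       recall = if (dr > 0) counts$TP / dr else 0,
       degenerate = dp == 0 || dr == 0)
}

#' Mean absolute error
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @return `mean(abs(predicted - reference))` in the input units.
#' @export
mae <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("length mismatch: ", length(predicted), " vs ", length(reference))
  if (!length(predicted)) stop("empty input")
  mean(abs(predicted - reference))
}

#' Pearson correlation between predicted and reference values
#'
#' @param predicted,reference Numeric vectors, length >= 2, non-constant.
#' @return Sample correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (length(predicted) < 2) stop("need at least 2 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0)
    stop("undefined correlation: constant input")
  stats::cor(predicted, reference)
}

#' Center-position error of a track against ground truth
#'
#' Per-frame Euclidean distance between predicted and true centers on the
#' overlapping frames, and the RMSE over all frames or a window.
#'
#' @param pred Data.frame `frame, cx, cy` (predicted centers).
#' @param truth Data.frame `frame, cx, cy` (true centers).
#' @param window Optional inclusive frame range `c(from, to)`.
#' @return List `rmse`, `errors` (data.frame `frame, err`).
#' @export
center_rmse <- function(pred, truth, window = NULL) {
  m <- merge(pred, truth, by = "frame", suffixes = c("", ".gt"))
  if (!is.null(window))
    m <- m[m$frame >= window[1] & m$frame <= window[2], , drop = FALSE]
  if (!nrow(m)) stop("no overlapping frames")
  err <- sqrt((m$cx - m$cx.gt)^2 + (m$cy - m$cy.gt)^2)
  list(rmse = sqrt(mean(err^2)),
       errors = data.frame(frame = m$frame, err = err))
}

#' CLEAR-MOT and identity metrics
#'
#' Per frame, ground-truth objects are matched one-to-one to hypothesis
#' boxes at IoU >= `iou_threshold`: correspondences persisting from the
#' previous frame are kept when still valid, the remainder is matched by
#' minimal total (1 - IoU) cost. An identity switch is counted whenever a
#' ground-truth trajectory's matched track id differs from its last known
#' one. `MOTA = 1 - (FN + FP + IDSW) / n_gt`. Identity scores assign whole
#' trajectories by maximizing the total per-frame overlap (IDTP);
#' `IDF1 = 2 IDTP / (len_gt + len_pred)`.
#'
#' @param tracks Track records `frame, track_id, x, y, w, h`.
#' @param gt Ground-truth records `frame, id, x, y, w, h`.
#' @param iou_threshold Match threshold (default 0.5).
#' @return List `mota, idf1, id_switches, fn, fp, n_gt, idtp`.
#' @export
mot_metrics <- function(tracks, gt, iou_threshold = 0.5) {
  frames <- sort(unique(c(tracks$frame, gt$frame)))
  gids <- sort(unique(gt$id)); hids <- sort(unique(tracks$track_id))
  fn <- 0L; fp <- 0L; idsw <- 0L; ngt <- 0L
  last_match <- stats::setNames(rep(NA_integer_, length(gids)), gids)
  prev <- list()   # gt id (char) -> track id, matches of previous frame
  overlap <- matrix(0L, length(gids), length(hids),
                    dimnames = list(gids, hids))
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- tracks[tracks$frame == f, , drop = FALSE]
    ngt <- ngt + nrow(g)
    iou <- matrix(0, nrow(g), nrow(h))
    if (nrow(g) && nrow(h))
      for (i in seq_len(nrow(g)))
        for (j in seq_len(nrow(h)))
          iou[i, j] <- box_iou(det_box(g[i, ]), det_box(h[j, ]))
    # identity-overlap counts for IDF1 (any pair above threshold)
    if (nrow(g) && nrow(h)) {
      for (i in seq_len(nrow(g)))
        for (j in seq_len(nrow(h)))
          if (iou[i, j] >= iou_threshold) {
            overlap[as.character(g$id[i]), as.character(h$track_id[j])] <-
              overlap[as.character(g$id[i]), as.character(h$track_id[j])] + 1L
          }
    }
    cur <- list()
    gleft <- seq_len(nrow(g)); hleft <- seq_len(nrow(h))
    # carry over persisting correspondences
    for (gi in seq_len(nrow(g))) {
      gid <- as.character(g$id[gi])
      tid <- prev[[gid]]
      if (is.null(tid)) next
      hj <- which(h$track_id == tid)
      if (length(hj) == 1L && iou[gi, hj] >= iou_threshold) {
        cur[[gid]] <- tid
        gleft <- setdiff(gleft, gi); hleft <- setdiff(hleft, hj)
      }
    }
    # match the remainder minimizing total 1 - IoU
    if (length(gleft) && length(hleft)) {
      cost <- matrix(Inf, length(gleft), length(hleft))
      for (a in seq_along(gleft))
        for (b in seq_along(hleft))
          if (iou[gleft[a], hleft[b]] >= iou_threshold)
            cost[a, b] <- 1 - iou[gleft[a], hleft[b]]
      asg <- solve_assignment(cost)
      for (a in seq_along(asg)) {
        if (is.na(asg[a])) next
        gid <- as.character(g$id[gleft[a]])
        cur[[gid]] <- h$track_id[hleft[asg[a]]]
      }
      matched_h <- as.integer(stats::na.omit(asg))
      if (length(matched_h)) hleft <- hleft[-matched_h]
      gleft <- gleft[is.na(asg)]
    }
    fn <- fn + length(gleft)
    fp <- fp + length(hleft)
    for (gid in names(cur)) {
      lm <- last_match[[gid]]
      if (!is.na(lm) && lm != cur[[gid]]) idsw <- idsw + 1L
      last_match[[gid]] <- cur[[gid]]
    }
    prev <- cur
  }
  # trajectory-level identity assignment maximizing total overlap
  idtp <- 0L
  if (length(gids) && length(hids)) {
    asg <- solve_assignment(-overlap)
    for (i in seq_along(asg))
      if (!is.na(asg[i])) idtp <- idtp + overlap[i, asg[i]]
  }
  len_gt <- nrow(gt); len_pr <- nrow(tracks)
  list(mota = if (ngt > 0) 1 - (fn + fp + idsw) / ngt else NA_real_,
       idf1 = if (len_gt + len_pr > 0) 2 * idtp / (len_gt + len_pr) else NA_real_,
       id_switches = idsw, fn = fn, fp = fp, n_gt = ngt, idtp = as.integer(idtp))
}

#' Evaluate height estimates against true heights
#'
#' @param predicted,reference Paired height vectors (meters).
#' @return List `mae_cm`, `pearson_r`, `n`.
#' @export
height_eval <- function(predicted, reference) {
  list(mae_cm = mae(predicted, reference) * 100,
       pearson_r = pearson_r(predicted, reference),
       n = length(predicted))
}
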