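# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (dense textbook algebra, permutation
# enumeration) and never share code with the package's own paths.

# plain textbook Kalman step: no symmetrization, straight formulas
textbook_kalman_step <- function(mean, cov, F, Q, H, R, z) {
  mean <- F %*% mean
  cov <- F %*% cov %*% t(F) + Q
  if (!is.null(z)) {
    S <- H %*% cov %*% t(H) + R
    K <- cov %*% t(H) %*% solve(S)
    mean <- mean + K %*% (z - H %*% mean)
    cov <- (diag(nrow(cov)) - K %*% H) %*% cov
  }
  list(mean = drop(mean), cov = cov)
}

# process-noise covariance as the filter defines it (std proportional to h)
oracle_process_noise <- function(h, w_pos = 1 / 20, w_vel = 1 / 160) {
  diag(c(w_pos * h, w_pos * h, 1e-2, w_pos * h,
         w_vel * h, w_vel * h, 1e-5, w_vel * h)^2)
}

# minimum-cost assignment by exhaustive enumeration (rows <= ~6)
brute_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  best <- NULL; best_cost <- Inf; best_n <- -1L
  cols <- seq_len(nc)
  # enumerate all injective partial maps rows -> cols (NA allowed)
  opts <- c(NA_integer_, cols)
  grid <- do.call(expand.grid, rep(list(opts), nr))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[!is.na(a)]
    if (anyDuplicated(used)) next
    cst <- 0; feasible <- TRUE; n_assigned <- 0L
    for (i in seq_len(nr)) {
      if (is.na(a[i])) next
      if (!is.finite(cost[i, a[i]])) { feasible <- FALSE; break }
      cst <- cst + cost[i, a[i]]; n_assigned <- n_assigned + 1L
    }
    if (!feasible) next
    # maximize cardinality first, then minimize cost (matches Hungarian
    # with finite costs; forbidden pairs stay unassigned)
    if (n_assigned > best_n || (n_assigned == best_n && cst < best_cost - 1e-12)) {
      best <- a; best_cost <- cst; best_n <- n_assigned
    }
  }
  best
}

# reference CLEAR-MOT + IDF1 using brute-force matching; same conventions
# as the package (carry-over, then min-cost completion at IoU >= thr)
ref_mot_metrics <- function(tracks, gt, thr = 0.5) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    u <- a[3] * a[4] + b[3] * b[4] - inter
    if (u <= 0) 0 else inter / u
  }
  frames <- sort(unique(c(tracks$frame, gt$frame)))
  fn <- 0L; fp <- 0L; idsw <- 0L; ngt <- 0L
  last <- list(); prev <- list()
  gids <- sort(unique(gt$id)); hids <- sort(unique(tracks$track_id))
  ov <- matrix(0L, length(gids), length(hids))
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- tracks[tracks$frame == f, , drop = FALSE]
    ngt <- ngt + nrow(g)
    iou <- matrix(0, nrow(g), nrow(h))
    for (i in seq_len(nrow(g)))
      for (j in seq_len(nrow(h))) {
        iou[i, j] <- iou1(as.numeric(g[i, c("x", "y", "w", "h")]),
                          as.numeric(h[j, c("x", "y", "w", "h")]))
        if (iou[i, j] >= thr)
          ov[match(g$id[i], gids), match(h$track_id[j], hids)] <-
            ov[match(g$id[i], gids), match(h$track_id[j], hids)] + 1L
      }
    cur <- list()
    gleft <- seq_len(nrow(g)); hleft <- seq_len(nrow(h))
    for (gi in seq_len(nrow(g))) {
      gid <- as.character(g$id[gi]); tid <- prev[[gid]]
      if (is.null(tid)) next
      hj <- which(h$track_id == tid)
      if (length(hj) == 1 && iou[gi, hj] >= thr) {
        cur[[gid]] <- tid
        gleft <- setdiff(gleft, gi); hleft <- setdiff(hleft, hj)
      }
    }
    if (length(gleft) && length(hleft)) {
      cost <- matrix(Inf, length(gleft), length(hleft))
      for (a in seq_along(gleft))
        for (b in seq_along(hleft))
          if (iou[gleft[a], hleft[b]] >= thr)
            cost[a, b] <- 1 - iou[gleft[a], hleft[b]]
      asg <- brute_assignment(cost)
      keep_h <- integer(0)
      for (a in seq_along(asg)) {
        if (is.na(asg[a])) next
        cur[[as.character(g$id[gleft[a]])]] <- h$track_id[hleft[asg[a]]]
        keep_h <- c(keep_h, asg[a])
      }
      if (length(keep_h)) hleft <- hleft[-keep_h]
      gleft <- gleft[is.na(asg)]
    }
    fn <- fn + length(gleft); fp <- fp + length(hleft)
    for (gid in names(cur)) {
      if (!is.null(last[[gid]]) && last[[gid]] != cur[[gid]]) idsw <- idsw + 1L
      last[[gid]] <- cur[[gid]]
    }
    prev <- cur
  }
  idtp <- if (length(gids) && length(hids)) {
    asg <- brute_assignment(-ov)
    s <- 0L
    for (i in seq_along(asg)) if (!is.na(asg[i])) s <- s + ov[i, asg[i]]
    s
  } else 0L
  list(mota = 1 - (fn + fp + idsw) / ngt,
       idf1 = 2 * idtp / (nrow(gt) + nrow(tracks)),
       id_switches = idsw, fn = fn, fp = fp)
}
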