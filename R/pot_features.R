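#' PoT extraction configuration
#'
#' @param n PoT length in frames (descriptor dimension is `2*(n-1)+1`)
#' @param theta_F frame pruning threshold on the windowed articulation score
#' @param theta_P fraction of top-scoring candidate pairs retained per frame
#' @return a `pot_config` list
#' @export
pot_config <- function(n = 10, theta_F = 0.1, theta_P = 0.15) {
  stopifnot(n >= 2, theta_P > 0, theta_P <= 1, theta_F >= 0)
  structure(list(n = as.integer(n), theta_F = theta_F, theta_P = theta_P),
            class = "pot_config")
}

#' Per-frame foreground flow statistics
#'
#' For each frame computes the median foreground velocity `v_m` (per-axis
#' median of the flow over mask pixels), the normalized flow spread
#' `sigma` (population standard deviation of the flow displacement
#' magnitudes over mask pixels, divided by their mean; defined as 0 when the
#' mean magnitude is below 1e-6), and the windowed articulation score
#' `s(f)`, the mean of `sigma` over frames `[f, f+n-1]`. Frames whose
#' window has `s(f) < theta_F` (or extends past the shot, or touches an
#' empty-mask frame) are marked pruned and yield no PoTs.
#'
#' @param flow list of H x W x 2 flow arrays, one per frame
#' @param masks list of logical masks, one per frame
#' @param config a [pot_config()]
#' @return a `pot_frame_stats` list with per-frame vectors `v_m` (frames x
#'   2), `sigma`, `s` and logical `pruned`
#' @export
frame_stats <- function(flow, masks, config = pot_config()) {
  stopifnot(length(flow) == length(masks))
  nf <- length(masks)
  v_m <- matrix(NA_real_, nf, 2)
  sigma <- rep(NA_real_, nf)
  for (t in seq_len(nf)) {
    sel <- which(masks[[t]])
    if (!length(sel)) next
    u <- flow[[t]][, , 1][sel]; v <- flow[[t]][, , 2][sel]
    v_m[t, ] <- c(stats::median(u), stats::median(v))
    mag <- sqrt(u * u + v * v)
    mu <- mean(mag)
    sigma[t] <- if (mu < 1e-6) 0 else
      sqrt(mean((mag - mu)^2)) / mu
  }
  n <- config$n
  s <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    if (f + n - 1 > nf) break
    win <- sigma[f:(f + n - 1)]
    if (!anyNA(win)) s[f] <- mean(win)
  }
  structure(list(v_m = v_m, sigma = sigma, s = s,
                 pruned = is.na(s) | s < config$theta_F, n = n),
            class = "pot_frame_stats")
}

# Velocities of all listed trajectories over the window [f, f+n-1]:
# per-frame displacements, with the last displacement reused for the final
# frame so the sum in the pair score runs over n terms.
window_velocities <- function(trajectories, f, n) {
  lapply(trajectories, function(tr) {
    p <- traj_window(tr, f, f + n - 1)
    d <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
    rbind(d, d[n - 1, , drop = FALSE])
  })
}

#' Score candidate trajectory pairs at one frame
#'
#' Scores every ordered pair of trajectories alive on `[f, f+n-1]` by how
#' much the swing's velocity deviates from the per-frame median foreground
#' velocity while the anchor's stays close to it:
#' `S = sum_k ||v_s^k - v_m^k|| - ||v_a^k - v_m^k||`. Swapping anchor and
#' swing negates the score, so both orderings of each unordered pair are
#' scored.
#'
#' @param trajectories list of trajectories
#' @param stats a `pot_frame_stats`
#' @param f 0-based start frame of the window
#' @param config a [pot_config()]
#' @return data frame with columns `anchor`, `swing` (indices into
#'   `trajectories`), `anchor_id`, `swing_id`, `score`; empty when fewer
#'   than two trajectories are alive
#' @export
score_candidates <- function(trajectories, stats, f, config = pot_config()) {
  n <- config$n
  alive <- which(vapply(trajectories, traj_alive, logical(1), f, f + n - 1))
  empty <- data.frame(anchor = integer(), swing = integer(),
                      anchor_id = integer(), swing_id = integer(),
                      score = numeric())
  if (length(alive) < 2) return(empty)
  vm <- stats$v_m[fr(f):fr(f + n - 1), , drop = FALSE]
  vm <- rbind(vm)
  if (anyNA(vm)) return(empty)
  vel <- window_velocities(trajectories[alive], f, n)
  # deviation of each trajectory from the median velocity, summed over window
  dev <- vapply(vel, function(v) sum(l2(v - vm)), numeric(1))
  m <- length(alive)
  pair <- expand.grid(anchor = seq_len(m), swing = seq_len(m))
  pair <- pair[pair$anchor != pair$swing, ]
  ids <- vapply(trajectories[alive], function(tr) tr$id, numeric(1))
  data.frame(anchor = alive[pair$anchor], swing = alive[pair$swing],
             anchor_id = ids[pair$anchor], swing_id = ids[pair$swing],
             score = dev[pair$swing] - dev[pair$anchor])
}

#' Select the top-scoring candidate pairs
#'
#' Keeps the `ceiling(theta_P * N)` highest-scoring ordered pairs for one
#' start frame. Ties at the cutoff are broken by (anchor id, swing id)
#' lexicographic order.
#'
#' @param scored data frame from [score_candidates()]
#' @param config a [pot_config()]
#' @return the retained subset of `scored`
#' @export
select_pots <- function(scored, config = pot_config()) {
  n_cand <- nrow(scored)
  if (n_cand == 0) return(scored)
  keep <- ceiling(config$theta_P * n_cand)
  ord <- order(-scored$score, scored$anchor_id, scored$swing_id)
  scored[ord[seq_len(keep)], , drop = FALSE]
}

#' PoT descriptor
#'
#' Builds the pair-of-trajectories descriptor over `[start_frame,
#' start_frame + n - 1]`: the angle from anchor to swing in the first frame,
#' followed by the sequence of relative displacement vectors
#' `d^k = r^k - r^(k-1)` (with `r^k` the anchor-to-swing vector at frame k),
#' each normalized by the total displacement `D = sum ||d^k||`. The
#' descriptor has length `2*(n-1)+1`, is invariant to camera panning
#' (a shared per-frame translation cancels in `r^k`) and to uniform scaling
#' (the angle and normalized steps are scale-free). Rigid pairs (`D = 0`)
#' carry no articulation signal and return NULL.
#'
#' @param anchor,swing trajectories alive on the window
#' @param start_frame 0-based window start
#' @param config a [pot_config()]
#' @return numeric descriptor of length `2*(n-1)+1`, or NULL when `D = 0`
#' @export
pot_descriptor <- function(anchor, swing, start_frame,
                           config = pot_config()) {
  n <- config$n
  if (!traj_alive(anchor, start_frame, start_frame + n - 1) ||
      !traj_alive(swing, start_frame, start_frame + n - 1))
    stop("trajectory does not cover the PoT window")
  r <- traj_window(swing, start_frame, start_frame + n - 1) -
    traj_window(anchor, start_frame, start_frame + n - 1)
  d <- r[-1, , drop = FALSE] - r[-n, , drop = FALSE]
  D <- sum(l2(d))
  if (D == 0) return(NULL)
  theta <- atan2(r[1, 2], r[1, 1])
  c(theta, as.vector(t(d / D)))
}

#' Extract PoTs from a shot
#'
#' The full extraction procedure: trajectories touching the background (any
#' point outside the mask in any frame of their span) are removed; frames are
#' pruned by the articulation score; for each retained start frame all
#' ordered pairs of alive trajectories are scored, the top fraction is kept,
#' and descriptors are computed (rigid pairs discarded).
#'
#' @param shot a `pot_shot` with trajectories, masks and flow
#' @param config a [pot_config()]
#' @param stats optional precomputed [frame_stats()]
#' @return a `pot_set`: list with `descriptors` (N x (2(n-1)+1) matrix) and
#'   `meta` (data frame anchor_id, swing_id, start_frame, score)
#' @export
extract_pots <- function(shot, config = pot_config(), stats = NULL) {
  if (is.null(shot$masks) || is.null(shot$flow))
    stop("PoT extraction requires masks and flow")
  stats <- stats %||% frame_stats(shot$flow, shot$masks, config)
  fg <- vapply(shot$trajectories, trajectory_on_foreground, logical(1),
               masks = shot$masks)
  trajs <- shot$trajectories[fg]
  n <- config$n
  desc <- list(); meta <- list()
  for (f in which(!stats$pruned) - 1L) {
    sel <- select_pots(score_candidates(trajs, stats, f, config), config)
    if (!nrow(sel)) next
    # batch descriptor computation for all selected pairs of this frame
    used <- sort(unique(c(sel$anchor, sel$swing)))
    win <- vapply(trajs[used], traj_window, matrix(0, n, 2), f, f + n - 1)
    ai <- match(sel$anchor, used); si <- match(sel$swing, used)
    rx <- t(win[, 1, si]) - t(win[, 1, ai])  # pairs x n
    ry <- t(win[, 2, si]) - t(win[, 2, ai])
    dx <- rx[, -1, drop = FALSE] - rx[, -n, drop = FALSE]
    dy <- ry[, -1, drop = FALSE] - ry[, -n, drop = FALSE]
    D <- rowSums(sqrt(dx^2 + dy^2))
    keep <- D > 0
    if (!any(keep)) next
    dd <- matrix(0, sum(keep), 2 * (n - 1))
    dd[, seq(1, by = 2, length.out = n - 1)] <- dx[keep, , drop = FALSE] / D[keep]
    dd[, seq(2, by = 2, length.out = n - 1)] <- dy[keep, , drop = FALSE] / D[keep]
    desc[[length(desc) + 1L]] <-
      cbind(atan2(ry[keep, 1], rx[keep, 1]), dd)
    meta[[length(meta) + 1L]] <- data.frame(
      anchor_id = sel$anchor_id[keep], swing_id = sel$swing_id[keep],
      start_frame = f, score = sel$score[keep])
  }
  structure(list(
    descriptors = if (length(desc)) do.call(rbind, desc) else
      matrix(numeric(), 0, 2 * (n - 1) + 1),
    meta = if (length(meta)) do.call(rbind, meta) else
      data.frame(anchor_id = integer(), swing_id = integer(),
                 start_frame = integer(), score = numeric()),
    n = n), class = "pot_set")
}

# A trajectory is a foreground trajectory iff every point of its span lies
# inside the mask of the corresponding frame.
trajectory_on_foreground <- function(tr, masks) {
  for (k in seq_len(nrow(tr$points))) {
    t <- tr$start + k - 1L
    if (t + 1L > length(masks)) return(FALSE)
    m <- masks[[t + 1L]]
    x <- round(tr$points[k, 1]) + 1; y <- round(tr$points[k, 2]) + 1
    if (x < 1 || x > ncol(m) || y < 1 || y > nrow(m) || !m[y, x])
      return(FALSE)
  }
  TRUE
}
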