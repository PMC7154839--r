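#' Motion boundary histogram descriptors at one frame
#'
#' For every foreground trajectory alive at frame `t`, computes orientation
#' histograms (8 bins for each of the two flow components) of the spatial
#' derivatives of the optical flow in a 16 x 16 patch centered on the track
#' point. Constant flow has zero derivatives everywhere, so the descriptor is
#' invariant to adding a global constant to the flow; energy concentrates in
#' the gradient direction across motion boundaries.
#'
#' @param shot a `pot_shot`
#' @param t 0-based frame index (flow at `t` maps frame `t` to `t+1`)
#' @param patch patch size in px
#' @return matrix (trajectories alive at `t`) x 16, with the trajectory ids
#'   in attribute `ids`
#' @export
mbh_descriptors <- function(shot, t, patch = 16) {
  fl <- shot$flow[[fr(t)]]
  h <- nrow(fl[, , 1]); w <- ncol(fl[, , 1])
  alive <- Filter(function(tr) traj_alive(tr, t, t), shot$trajectories)
  if (!length(alive))
    return(structure(matrix(numeric(), 0, 16), ids = integer()))
  half <- patch / 2
  desc <- matrix(0, length(alive), 16)
  for (i in seq_along(alive)) {
    p <- traj_window(alive[[i]], t, t)
    x0 <- clamp(round(p[1]) - half, 0, w - patch)
    y0 <- clamp(round(p[2]) - half, 0, h - patch)
    rows <- (y0 + 1):(y0 + patch); cols <- (x0 + 1):(x0 + patch)
    for (ch in 1:2) {
      f <- fl[rows, cols, ch]
      gx <- (f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE])[-1, ]
      gy <- (f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE])[, -1]
      mag <- sqrt(gx^2 + gy^2)
      ang <- atan2(gy, gx) %% (2 * pi)
      bin <- pmin(floor(ang / (2 * pi / 8)) + 1, 8)
      hbin <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1))
      if (sum(hbin) > 0) hbin <- hbin / sum(hbin)
      desc[i, (ch - 1) * 8 + 1:8] <- hbin
    }
  }
  structure(desc, ids = vapply(alive, function(tr) tr$id, numeric(1)))
}

#' Per-frame channel BoWs for an interval
#'
#' Builds, for each frame of the interval, the L1-normalized BoW of each
#' feature channel: the PoT channel aggregates the descriptors of PoTs
#' starting at that frame; the MBH channel aggregates the per-trajectory MBH
#' descriptors of that frame.
#'
#' @param shot a `pot_shot`
#' @param iv an [interval()]
#' @param pots a `pot_set` for the shot
#' @param pot_codebook,mbh_codebook codebooks for the two channels
#'   (`mbh_codebook = NULL` drops the MBH channel)
#' @return list of channels, each a (interval length) x V matrix
#' @export
frame_channel_bows <- function(shot, iv, pots, pot_codebook,
                               mbh_codebook = NULL) {
  frames <- iv$start:(iv$end - 1L)
  pot_mat <- t(vapply(frames, function(t) {
    sel <- pots$meta$start_frame == t
    bow(pots$descriptors[sel, , drop = FALSE], pot_codebook)
  }, numeric(nrow(pot_codebook$centroids))))
  channels <- list(pot = pot_mat)
  if (!is.null(mbh_codebook)) {
    channels$mbh <- t(vapply(frames, function(t) {
      bow(mbh_descriptors(shot, t), mbh_codebook)
    }, numeric(nrow(mbh_codebook$centroids))))
  }
  channels
}

#' Frame-to-frame distance matrix between two intervals
#'
#' Entry (i, j) is the multichannel exponential histogram-intersection
#' distance between the frame-i BoWs of the first interval and the frame-j
#' BoWs of the second. Frames with an empty BoW in any channel are maximally
#' dissimilar (`-exp(-1)`).
#'
#' @param channels_p,channels_q per-frame channel BoWs
#'   ([frame_channel_bows()])
#' @param A channel scales (defaults to 1 per channel)
#' @return matrix (frames of p) x (frames of q) with entries in
#'   `[-1, -exp(-1)]`
#' @export
frame_distance_matrix <- function(channels_p, channels_q, A = NULL) {
  stopifnot(length(channels_p) == length(channels_q))
  A <- A %||% rep(1, length(channels_p))
  np <- nrow(channels_p[[1]]); nq <- nrow(channels_q[[1]])
  s <- matrix(0, np, nq)
  empty <- matrix(FALSE, np, nq)
  for (c in seq_along(channels_p)) {
    P <- channels_p[[c]]; Q <- channels_q[[c]]
    if (ncol(P) != ncol(Q)) stop("channel ", c, " has mismatched V")
    hi <- matrix(0, np, nq)
    for (i in seq_len(np)) hi[i, ] <- colSums(pmin(t(Q), P[i, ]))
    s <- s + (1 - hi) / A[c]
    empty <- empty | outer(rowSums(P) == 0, rowSums(Q) == 0, `|`)
  }
  d <- -exp(-s)
  d[empty] <- -exp(-1)
  d
}

#' Extract consistent motion pairs from a frame distance matrix
#'
#' Scores every pair of temporally aligned T-frame subsequences (one from
#' each interval) by the sum of per-frame distances along the diagonal
#' (temporal order preserved) and returns the `top_k` most similar (most
#' negative) pairs. Near-duplicate pairs whose two start offsets both lie
#' within T/2 of an already selected pair are suppressed. Ties are broken by
#' (i, j) lexicographic order.
#'
#' @param dmat frame distance matrix ([frame_distance_matrix()])
#' @param T subsequence length in frames
#' @param top_k number of CMPs to return
#' @return list of `list(start_p, start_q, T, score)` with 0-based offsets
#'   into the two intervals; attribute `n_candidates` holds the number of
#'   scored pairs `(n-T)*(m-T)`
#' @export
extract_cmps <- function(dmat, T = 10, top_k = 10) {
  stopifnot(T >= 2)
  n <- nrow(dmat); m <- ncol(dmat)
  if (n - T < 1 || m - T < 1)
    return(structure(list(), n_candidates = 0L))
  S <- matrix(0, n - T, m - T)
  for (t in 0:(T - 1))
    S <- S + dmat[(1:(n - T)) + t, (1:(m - T)) + t, drop = FALSE]
  cand <- expand.grid(i = 0:(n - T - 1), j = 0:(m - T - 1))
  cand$score <- S[cbind(cand$i + 1, cand$j + 1)]
  cand <- cand[order(cand$score, cand$i, cand$j), ]
  out <- list()
  for (r in seq_len(nrow(cand))) {
    if (length(out) >= top_k) break
    dup <- any(vapply(out, function(c)
      abs(c$start_p - cand$i[r]) < T / 2 && abs(c$start_q - cand$j[r]) < T / 2,
      logical(1)))
    if (dup) next
    out[[length(out) + 1L]] <- list(start_p = cand$i[r], start_q = cand$j[r],
                                    T = as.integer(T), score = cand$score[r])
  }
  structure(out, n_candidates = (n - T) * (m - T))
}
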