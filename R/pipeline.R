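#' Discover behaviors in a collection of shots
#'
#' Runs the discovery stages end to end: PoT extraction per shot, temporal
#' partitioning into single-behavior intervals, a shared PoT codebook,
#' interval BoW histograms and complete-linkage clustering.
#'
#' @param shots list of `pot_shot` objects
#' @param k number of behavior clusters (default: a fourth of the number of
#'   intervals, at least 2)
#' @param pot_cfg a [pot_config()]
#' @param part_cfg a [partition_config()]
#' @param V codebook size (capped at a fourth of the descriptor count)
#' @param seed codebook seed
#' @return list with `pots`, `stats` (per shot), `intervals` (flat),
#'   `interval_shot` (index of each interval's shot), `codebook`, `bows`,
#'   `clusters`
#' @export
discover_behaviors <- function(shots, k = NULL, pot_cfg = pot_config(),
                               part_cfg = partition_config(), V = 50,
                               seed = 1) {
  stats <- lapply(shots, function(s) frame_stats(s$flow, s$masks, pot_cfg))
  pots <- mapply(function(s, st) extract_pots(s, pot_cfg, st), shots, stats,
                 SIMPLIFY = FALSE)
  all_desc <- do.call(rbind, lapply(pots, `[[`, "descriptors"))
  if (is.null(all_desc) || nrow(all_desc) < 8)
    stop("too few PoTs extracted to discover behaviors")
  V <- max(2, min(V, floor(nrow(unique(all_desc)) / 4)))
  codebook <- build_codebook(all_desc, V = V, restarts = 8, seed = seed)

  intervals <- list(); interval_shot <- integer()
  for (i in seq_along(shots)) {
    ivs <- partition_shot(shots[[i]], pots[[i]], stats[[i]], part_cfg,
                          theta_F = pot_cfg$theta_F)
    intervals <- c(intervals, ivs)
    interval_shot <- c(interval_shot, rep(i, length(ivs)))
  }
  if (!length(intervals)) stop("no intervals found")

  bows <- t(mapply(function(iv, si) {
    sel <- pots[[si]]$meta$start_frame >= iv$start &
      pots[[si]]$meta$start_frame < iv$end
    bow(pots[[si]]$descriptors[sel, , drop = FALSE], codebook)
  }, intervals, interval_shot))
  if (is.null(dim(bows))) bows <- matrix(bows, nrow = length(intervals))

  k <- k %||% max(2, round(length(intervals) / 4))
  clusters <- cluster_intervals(bows, k = min(k, length(intervals)))
  list(pots = pots, stats = stats, intervals = intervals,
       interval_shot = interval_shot, codebook = codebook, bows = bows,
       clusters = clusters)
}

#' Extract CMPs between same-cluster intervals
#'
#' For every pair of intervals assigned to the same behavior cluster,
#' computes per-frame BoWs on the PoT channel (and optionally an MBH
#' channel with its own codebook), the frame distance matrix, and the top
#' consistent motion pairs.
#'
#' @param disc result of [discover_behaviors()]
#' @param shots the shot list given to [discover_behaviors()]
#' @param T CMP length in frames
#' @param top_k CMPs kept per interval pair
#' @param use_mbh add the motion-boundary-histogram channel
#' @param mbh_V MBH codebook size
#' @param seed codebook seed
#' @return list of CMP records: `list(p, q, shot_p, shot_q, start_p,
#'   start_q, T, score)` with absolute start frames
#' @export
extract_cluster_cmps <- function(disc, shots, T = 10, top_k = 3,
                                 use_mbh = TRUE, mbh_V = 30, seed = 1) {
  n <- length(disc$intervals)
  mbh_codebook <- NULL
  if (use_mbh) {
    samp <- list()
    for (i in seq_len(n)) {
      iv <- disc$intervals[[i]]; si <- disc$interval_shot[i]
      for (t in seq(iv$start, iv$end - 1, by = max(1, (iv$end - iv$start) %/% 3)))
        samp[[length(samp) + 1L]] <- mbh_descriptors(shots[[si]], t)
    }
    samp <- do.call(rbind, samp)
    if (nrow(unique(samp)) > 2 * mbh_V)
      mbh_codebook <- build_codebook(samp,
                                     V = min(mbh_V,
                                             floor(nrow(unique(samp)) / 2)),
                                     restarts = 2, seed = seed)
  }
  chans <- lapply(seq_len(n), function(i)
    frame_channel_bows(shots[[disc$interval_shot[i]]], disc$intervals[[i]],
                       disc$pots[[disc$interval_shot[i]]], disc$codebook,
                       mbh_codebook))
  nchan <- length(chans[[1]])
  A <- channel_scales(lapply(seq_len(nchan), function(c)
    do.call(rbind, lapply(chans, `[[`, c))))

  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(disc$clusters[i]) || is.na(disc$clusters[j]) ||
        disc$clusters[i] != disc$clusters[j]) next
    dmat <- frame_distance_matrix(chans[[i]], chans[[j]], A)
    for (cmp in extract_cmps(dmat, T = T, top_k = top_k)) {
      out[[length(out) + 1L]] <- list(
        p = i, q = j,
        shot_p = disc$interval_shot[i], shot_q = disc$interval_shot[j],
        start_p = disc$intervals[[i]]$start + cmp$start_p,
        start_q = disc$intervals[[j]]$start + cmp$start_q,
        T = cmp$T, score = cmp$score)
    }
  }
  out
}

# per-frame bbox corners over a CMP window
cmp_fg_boxes <- function(shot, start, T) {
  lapply(start:(start + T - 1), function(t) bbox_corners(shot$masks[[fr(t)]]))
}

#' Homography alignment of one CMP record
#'
#' @param shot_p,shot_q the two shots
#' @param cmp a CMP record ([extract_cluster_cmps()])
#' @param mode,use_fg,max_outlier_fraction,seed passed to [fit_homography()]
#' @return a `pot_homography` or NULL
#' @export
align_cmp_homography <- function(shot_p, shot_q, cmp, mode = "tm",
                                 use_fg = TRUE, max_outlier_fraction = 0.8,
                                 seed = 1) {
  matches <- match_trajectories(shot_p, shot_q, cmp$start_p, cmp$start_q,
                                cmp$T)
  fg <- list(u = cmp_fg_boxes(shot_p, cmp$start_p, cmp$T),
             v = cmp_fg_boxes(shot_q, cmp$start_q, cmp$T))
  fit_homography(matches, fg_boxes = fg, mode = mode, use_fg = use_fg,
                 max_outlier_fraction = max_outlier_fraction, seed = seed)
}

#' Temporal TPS alignment of one CMP record
#'
#' Builds per-frame foreground edge sets (mask-silhouette gradient by
#' default), slices the flow windows and refines the homography
#' initialization with [fit_ttps()].
#'
#' @param shot_p,shot_q the two shots
#' @param cmp a CMP record
#' @param init_H 3 x 3 homography initialization (or NULL)
#' @param max_points edge points kept per frame
#' @param seed subsampling seed
#' @param ... passed to [fit_ttps()]
#' @return a `pot_ttps` or NULL
#' @export
align_cmp_ttps <- function(shot_p, shot_q, cmp, init_H = NULL,
                           max_points = 150, seed = 1, ...) {
  edge_sets <- function(shot, start) {
    lapply(start:(start + cmp$T - 1), function(t) {
      m <- shot$masks[[fr(t)]]
      extract_foreground_edges(edge_strength(m * 1), m, seed = seed)
    })
  }
  flow_win <- function(shot, start)
    shot$flow[fr(start):fr(start + cmp$T - 1)]
  fit_ttps(edge_sets(shot_p, cmp$start_p), edge_sets(shot_q, cmp$start_q),
           flow_win(shot_p, cmp$start_p), flow_win(shot_q, cmp$start_q),
           init_H = init_H, max_points = max_points, seed = seed, ...)
}

# landmarks of a CMP window, re-indexed to frames 0..T-1
cmp_landmarks <- function(shot, start, T) {
  lm <- shot$landmarks[shot$landmarks$frame >= start &
                         shot$landmarks$frame < start + T, ]
  lm$frame <- lm$frame - start
  lm
}

#' Evaluate an alignment of one CMP record against landmarks
#'
#' @param shot_p,shot_q the two shots (with landmark annotations)
#' @param cmp a CMP record
#' @param alignment a `pot_homography` or `pot_ttps` (NULL allowed)
#' @return list with `error`, `iou`, `correct`, `alignable`
#' @export
evaluate_cmp <- function(shot_p, shot_q, cmp, alignment) {
  l1 <- cmp_landmarks(shot_p, cmp$start_p, cmp$T)
  l2 <- cmp_landmarks(shot_q, cmp$start_q, cmp$T)
  orc <- alignable_oracle(l1, l2, cmp$T)
  if (is.null(alignment))
    return(list(error = NA_real_, iou = NA_real_, correct = FALSE,
                alignable = orc$alignable))
  err <- alignment_error(alignment, l1, l2, cmp$T)
  v <- verdict(err, l1, l2)
  list(error = err, iou = v$iou, correct = v$correct,
       alignable = orc$alignable)
}
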