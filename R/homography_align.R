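#' Apply a homography to points
#' @param H 3x3 matrix
#' @param pts n x 2 points
#' @return n x 2 mapped points
#' @export
apply_homography <- function(H, pts) {
  pts <- as_pts(pts)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2] / ph[, 3]
}

# Normalized DLT least-squares fit of H with dst ~ H src (dst = u, src = v).
dlt_fit <- function(src, dst) {
  src <- as_pts(src); dst <- as_pts(dst)
  n <- nrow(src)
  stopifnot(n >= 4, nrow(dst) == n)
  norm_T <- function(p) {
    c0 <- colMeans(p)
    s <- sqrt(2) / max(mean(sqrt(rowSums(sweep(p, 2, c0)^2))), 1e-12)
    matrix(c(s, 0, 0, 0, s, 0, -s * c0[1], -s * c0[2], 1), 3, 3)
  }
  Ts <- norm_T(src); Td <- norm_T(dst)
  s <- apply_homography(Ts, src); d <- apply_homography(Td, dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% H %*% Ts
  normalize_homography(H)
}

normalize_homography <- function(H) {
  H <- H / sqrt(sum(H^2))
  pivot <- if (abs(H[3, 3]) > 1e-12) H[3, 3] else H[which(abs(H) > 1e-12)[1]]
  if (pivot < 0) H <- -H
  H
}

# any 3 of the 4 sampled points (nearly) collinear?
degenerate_sample <- function(p) {
  for (cmb in utils::combn(nrow(p), 3, simplify = FALSE)) {
    a <- p[cmb[1], ]; b <- p[cmb[2], ]; c <- p[cmb[3], ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cr) < 1e-6 * max(1, sum(abs(b - a)) * sum(abs(c - a))))
      return(TRUE)
  }
  FALSE
}

#' Modified trajectory-shape descriptor
#'
#' The trajectory-shape descriptor (the concatenated frame-to-frame
#' displacement vectors of one trajectory over T frames) is made more
#' discriminative by appending the vector from the trajectory's start point
#' to the center of mass of the foreground mask in the start frame,
#' normalized by the diagonal of the mask's bounding box so that the
#' appended part is scale invariant.
#'
#' @param traj a trajectory alive on `[start_frame, start_frame + T - 1]`
#' @param masks per-frame masks of the trajectory's shot
#' @param start_frame 0-based start of the window
#' @param T window length in frames
#' @return numeric vector of length `2*(T-1) + 2`
#' @export
modified_ts_descriptor <- function(traj, masks, start_frame, T = 10) {
  if (!traj_alive(traj, start_frame, start_frame + T - 1))
    stop("trajectory does not cover the window")
  m <- masks[[fr(start_frame)]]
  if (!any(m)) stop("empty mask at the descriptor start frame")
  p <- traj_window(traj, start_frame, start_frame + T - 1)
  d <- p[-1, , drop = FALSE] - p[-T, , drop = FALSE]
  com <- mask_centroid(m)
  v <- (unname(com) - p[1, ]) / bbox_diag(m)
  c(as.vector(t(d)), v)
}

#' Match trajectories between the two sequences of a CMP
#'
#' Each eligible trajectory of the first sequence (on the foreground and
#' spanning the whole T-frame window) is matched to its nearest neighbor in
#' the second sequence by Euclidean distance between modified
#' trajectory-shape descriptors; only windows starting at the same
#' within-CMP frame are compared, so each match yields T point
#' correspondences, one per frame. Many-to-one matches are allowed.
#'
#' @param shot_u,shot_v the two shots
#' @param start_u,start_v 0-based start frames of the CMP subsequences
#' @param T window length in frames
#' @return list of matches `list(index_u, index_v, dist, points_u,
#'   points_v)` with `points_*` T x 2 matrices
#' @export
match_trajectories <- function(shot_u, shot_v, start_u, start_v, T = 10) {
  eligible <- function(shot, start) {
    which(vapply(shot$trajectories, function(tr)
      traj_alive(tr, start, start + T - 1) &&
        trajectory_window_on_fg(tr, shot$masks, start, T), logical(1)))
  }
  eu <- eligible(shot_u, start_u); ev <- eligible(shot_v, start_v)
  if (!length(eu) || !length(ev)) return(list())
  du <- t(vapply(shot_u$trajectories[eu], modified_ts_descriptor,
                 numeric(2 * (T - 1) + 2), masks = shot_u$masks,
                 start_frame = start_u, T = T))
  dv <- t(vapply(shot_v$trajectories[ev], modified_ts_descriptor,
                 numeric(2 * (T - 1) + 2), masks = shot_v$masks,
                 start_frame = start_v, T = T))
  d2 <- outer(rowSums(du^2), rep(1, nrow(dv))) - 2 * du %*% t(dv) +
    outer(rep(1, nrow(du)), rowSums(dv^2))
  nn <- max.col(-d2, ties.method = "first")
  lapply(seq_along(eu), function(i) {
    list(index_u = eu[i], index_v = ev[nn[i]],
         dist = sqrt(max(d2[i, nn[i]], 0)),
         points_u = traj_window(shot_u$trajectories[[eu[i]]], start_u,
                                start_u + T - 1),
         points_v = traj_window(shot_v$trajectories[[ev[nn[i]]]], start_v,
                                start_v + T - 1))
  })
}

trajectory_window_on_fg <- function(tr, masks, start, T) {
  for (t in start:(start + T - 1)) {
    m <- masks[[fr(t)]]
    p <- traj_window(tr, t, t)
    x <- round(p[1]) + 1; y <- round(p[2]) + 1
    if (x < 1 || x > ncol(m) || y < 1 || y > nrow(m) || !m[y, x])
      return(FALSE)
  }
  TRUE
}

# 4 bbox corners of a mask, clockwise from top-left, as a 4 x 2 matrix
bbox_corners <- function(mask) {
  b <- mask_bbox(mask)
  rbind(c(b["xmin"], b["ymin"]), c(b["xmax"], b["ymin"]),
        c(b["xmax"], b["ymax"]), c(b["xmin"], b["ymax"]))
}

#' Fit a homography to trajectory matches with RANSAC
#'
#' Estimates the homography mapping the second sequence onto the first from
#' trajectory matches. Two sampling modes: `"im"` (independent matching)
#' treats all T x M point correspondences independently and samples 4
#' points per iteration; `"tm"` (temporal matching) samples 4 trajectory
#' matches and fits the sample in least squares over their 4T points, and a
#' match counts as an inlier only if more than half of its point
#' correspondences are inliers. With `use_fg`, the per-frame foreground
#' bounding-box corner correspondences are added to every least-squares fit
#' as a regularizer (and the fit degenerates gracefully to the bbox-only
#' solution when there are no matches). Returns NULL when the best model's
#' outlier fraction exceeds `max_outlier_fraction`.
#'
#' @param matches list from [match_trajectories()]
#' @param fg_boxes optional `list(u = , v = )` of per-frame 4 x 2 bbox
#'   corner matrices for the two sequences
#' @param mode `"tm"` or `"im"`
#' @param use_fg add bbox-corner correspondences to the objective
#' @param max_outlier_fraction reject models with a higher outlier fraction
#' @param inlier_threshold reprojection threshold in px; defaults to
#'   0.05 x the mean foreground bbox diagonal of the first sequence
#' @param seed RANSAC seed
#' @param max_iter iteration ceiling (adaptive below it, 0.99 confidence)
#' @return a `pot_homography` (fields `H`, `inliers`, `outlier_fraction`,
#'   `mode`, `fg_regularized`) or NULL
#' @export
fit_homography <- function(matches, fg_boxes = NULL,
                           mode = c("tm", "im"), use_fg = FALSE,
                           max_outlier_fraction = 0.8,
                           inlier_threshold = NULL, seed = 1,
                           max_iter = 2000) {
  mode <- match.arg(mode)
  if (use_fg && is.null(fg_boxes))
    stop("use_fg requires fg_boxes")
  fg_u <- NULL; fg_v <- NULL
  if (use_fg) {
    fg_u <- do.call(rbind, fg_boxes$u)
    fg_v <- do.call(rbind, fg_boxes$v)
  }
  if (is.null(inlier_threshold)) {
    if (is.null(fg_boxes)) stop("need fg_boxes or an explicit inlier_threshold")
    diags <- vapply(fg_boxes$u, function(cn)
      sqrt(sum((cn[3, ] - cn[1, ])^2)), numeric(1))
    inlier_threshold <- 0.05 * mean(diags)
  }

  fit_ls <- function(src, dst) {
    if (use_fg) dlt_fit(rbind(src, fg_v), rbind(dst, fg_u))
    else dlt_fit(src, dst)
  }

  nm <- length(matches)
  if (nm == 0) {
    if (!use_fg) return(NULL)
    H <- dlt_fit(fg_v, fg_u)  # FG baseline: bbox corners only
    return(structure(list(H = H, inliers = integer(), outlier_fraction = 0,
                          mode = mode, fg_regularized = TRUE,
                          inlier_threshold = inlier_threshold),
                     class = "pot_homography"))
  }
  U <- do.call(rbind, lapply(matches, `[[`, "points_u"))
  V <- do.call(rbind, lapply(matches, `[[`, "points_v"))
  T <- nrow(matches[[1]]$points_u)
  match_of_point <- rep(seq_len(nm), each = T)

  point_inliers <- function(H) {
    err <- l2(apply_homography(H, V) - U)
    err < inlier_threshold
  }
  score_model <- function(H) {
    pin <- point_inliers(H)
    if (mode == "im") {
      list(n = sum(pin), frac = 1 - mean(pin), match_in = NULL, pin = pin)
    } else {
      min_in <- tapply(pin, match_of_point, sum) > T / 2
      list(n = sum(min_in), frac = 1 - mean(min_in),
           match_in = which(as.vector(min_in)), pin = pin)
    }
  }

  set.seed(seed)
  n_units <- if (mode == "im") nrow(U) else nm
  best <- NULL; best_H <- NULL
  iter_needed <- max_iter
  it <- 0
  while (it < min(iter_needed, max_iter)) {
    it <- it + 1
    take <- sample(n_units, min(4, n_units))
    if (mode == "im") {
      src <- V[take, , drop = FALSE]; dst <- U[take, , drop = FALSE]
      check <- src
    } else {
      sel <- match_of_point %in% take
      src <- V[sel, , drop = FALSE]; dst <- U[sel, , drop = FALSE]
      # degeneracy is judged on one point per sampled trajectory: a single
      # trajectory's points are typically near-collinear by themselves
      check <- V[match(take, match_of_point), , drop = FALSE]
    }
    if (nrow(check) >= 4 && degenerate_sample(check))
      next
    H <- tryCatch(fit_ls(src, dst), error = function(e) NULL)
    if (is.null(H)) next
    sc <- score_model(H)
    if (is.null(best) || sc$n > best$n) {
      best <- sc; best_H <- H
      w <- max(1 - sc$frac, 1e-3)
      iter_needed <- min(max_iter,
                         ceiling(log(0.01) / log(pmax(1 - w^4, 1e-12))))
    }
  }
  if (is.null(best)) return(NULL)
  # final least-squares refit on all inlier correspondences (+ fg corners)
  keep <- if (mode == "im") best$pin else match_of_point %in% best$match_in
  if (sum(keep) >= 4) {
    H2 <- tryCatch(fit_ls(V[keep, , drop = FALSE], U[keep, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(H2)) {
      sc2 <- score_model(H2)
      if (sc2$n >= best$n) { best <- sc2; best_H <- H2 }
    }
  }
  if (best$frac > max_outlier_fraction) return(NULL)
  structure(list(H = best_H,
                 inliers = if (mode == "im") which(best$pin) else
                   best$match_in,
                 outlier_fraction = best$frac, mode = mode,
                 fg_regularized = use_fg,
                 inlier_threshold = inlier_threshold),
            class = "pot_homography")
}
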