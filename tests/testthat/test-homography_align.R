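# synthetic trajectory matches related by a known homography
make_matches <- function(H, n_in, n_out = 0, noise = 0, T = 10, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_in + n_out), function(i) {
    v0 <- c(stats::runif(1, 20, 180), stats::runif(1, 20, 80))
    vel <- stats::runif(2, -1.5, 1.5)
    pv <- cbind(v0[1] + vel[1] * (0:(T - 1)), v0[2] + vel[2] * (0:(T - 1)))
    pu <- apply_homography(H, pv) +
      matrix(stats::rnorm(2 * T, 0, noise), T, 2)
    if (i > n_in) pu <- pu + matrix(stats::runif(2 * T, 15, 40), T, 2)
    list(points_u = pu, points_v = pv)
  })
}

H_TEST <- potkit:::normalize_homography(
  matrix(c(1.05, 0.02, 1e-4, -0.03, 0.98, -5e-5, 8, -5, 1), 3, 3,
         byrow = FALSE))
GRID <- as.matrix(expand.grid(seq(20, 180, 20), seq(20, 80, 15)))
grid_err <- function(H, H_ref = H_TEST) {
  max(sqrt(rowSums((apply_homography(H, GRID) -
                      apply_homography(H_ref, GRID))^2)))
}

test_that("the modified trajectory-shape descriptor encodes shape plus mask context", {
  T <- 10
  mask <- matrix(FALSE, 60, 80); mask[21:40, 31:50] <- TRUE
  masks <- rep(list(mask), T)
  tr <- line_traj(1, 0, c(35, 25), c(1.5, -0.5), T)
  d <- modified_ts_descriptor(tr, masks, 0, T)
  expect_length(d, 2 * (T - 1) + 2)
  expect_equal(d[1:(2 * (T - 1))], rep(c(1.5, -0.5), T - 1))
  # a trajectory starting at the mask centroid has a zero appended vector
  com <- potkit:::mask_centroid(mask)
  tc <- line_traj(2, 0, com, c(1, 0), T)
  expect_equal(tail(modified_ts_descriptor(tc, masks, 0, T), 2), c(0, 0),
               ignore_attr = TRUE)
  # uniform scaling leaves the appended (normalized) vector unchanged, up
  # to the half-pixel discretization of the doubled mask
  mask2 <- matrix(FALSE, 120, 160); mask2[41:80, 61:100] <- TRUE
  tr2 <- tr; tr2$points <- tr2$points * 2
  d2 <- modified_ts_descriptor(tr2, rep(list(mask2), T), 0, T)
  expect_equal(tail(d2, 2), tail(d, 2), tolerance = 0.05)
  expect_error(modified_ts_descriptor(tr, rep(list(mask * FALSE), T), 0, T),
               "empty mask")
})

test_that("trajectory matching finds twins and equals brute-force search", {
  s <- tiny_shot()
  matches <- match_trajectories(s, s, 2, 2, T = 10)
  expect_gt(length(matches), 0)
  for (m in matches) {
    expect_equal(m$index_u, m$index_v)
    expect_lt(m$dist, 1e-6)
    expect_equal(dim(m$points_u), c(10, 2))
  }
  # brute-force check against an independently computed nearest neighbor
  s2 <- walk_scene()
  matches2 <- match_trajectories(s, s2, 2, 4, T = 10)
  d_of <- function(shot, idx, start) modified_ts_descriptor(
    shot$trajectories[[idx]], shot$masks, start, 10)
  for (m in matches2[1:5]) {
    du <- d_of(s, m$index_u, 2)
    cand <- vapply(seq_along(s2$trajectories), function(j) {
      dv <- tryCatch(d_of(s2, j, 4), error = function(e) NULL)
      if (is.null(dv)) return(Inf)
      if (!potkit:::trajectory_window_on_fg(s2$trajectories[[j]], s2$masks,
                                            4, 10)) return(Inf)
      sum((du - dv)^2)
    }, numeric(1))
    expect_equal(sum((du - d_of(s2, m$index_v, 4))^2), min(cand),
                 tolerance = 1e-12)
  }
})

test_that("noiseless matches recover the homography exactly in both modes", {
  for (mode in c("im", "tm")) {
    fit <- fit_homography(make_matches(H_TEST, 20, seed = 5), mode = mode,
                          inlier_threshold = 3, seed = 1)
    expect_lt(grid_err(fit$H), 1e-6)
    expect_equal(fit$outlier_fraction, 0)
  }
  # identity scene pair
  id_fit <- fit_homography(make_matches(diag(3), 15, seed = 6), mode = "tm",
                           inlier_threshold = 3, seed = 1)
  expect_lt(max(abs(apply_homography(id_fit$H, GRID) - GRID)), 1e-6)
})

test_that("RANSAC is robust to gross outliers and deterministic by seed", {
  ok <- 0
  for (trial in 1:20) {
    fit <- fit_homography(make_matches(H_TEST, 32, 8, noise = 1,
                                       seed = trial),
                          mode = "tm", inlier_threshold = 3, seed = trial,
                          max_outlier_fraction = 0.5)
    if (!is.null(fit) && grid_err(fit$H) < 2) ok <- ok + 1
  }
  expect_gte(ok, 19)
  m <- make_matches(H_TEST, 32, 8, noise = 1, seed = 3)
  f1 <- fit_homography(m, mode = "tm", inlier_threshold = 3, seed = 7)
  f2 <- fit_homography(m, mode = "tm", inlier_threshold = 3, seed = 7)
  expect_identical(f1$H, f2$H)
})

test_that("the temporal-matching inlier rule requires a majority of inlier points", {
  # one match with exactly half its points displaced: not an inlier;
  # with one fewer displaced point it becomes an inlier
  T <- 10
  good <- make_matches(H_TEST, 12, seed = 8, T = T)
  half_bad <- good[[1]]
  half_bad$points_u[1:5, ] <- half_bad$points_u[1:5, ] + 50
  fit <- fit_homography(c(good[-1], list(half_bad)), mode = "tm",
                        inlier_threshold = 3, seed = 1)
  expect_false(length(good) %in% fit$inliers)
  mostly_good <- good[[1]]
  mostly_good$points_u[1:4, ] <- mostly_good$points_u[1:4, ] + 50
  fit2 <- fit_homography(c(good[-1], list(mostly_good)), mode = "tm",
                         inlier_threshold = 3, seed = 1)
  expect_true(length(good) %in% fit2$inliers)
})

test_that("models beyond the allowed outlier fraction are rejected", {
  m <- make_matches(H_TEST, 10, 10, noise = 0.5, seed = 9)
  expect_null(fit_homography(m, mode = "tm", inlier_threshold = 3, seed = 1,
                             max_outlier_fraction = 0.2))
  expect_false(is.null(fit_homography(m, mode = "tm", inlier_threshold = 3,
                                      seed = 1,
                                      max_outlier_fraction = 0.6)))
})

test_that("foreground boxes regularize and provide the zero-match fallback", {
  # bbox corners mapped by the true homography, one box per frame
  T <- 10
  corners_v <- lapply(1:T, function(t)
    rbind(c(30, 25), c(170, 25), c(170, 85), c(30, 85)) + (t - 1))
  corners_u <- lapply(corners_v, function(cn) apply_homography(H_TEST, cn))
  fg <- list(u = corners_u, v = corners_v)
  # no matches at all: the bbox-only fit recovers the mapping
  fit0 <- fit_homography(list(), fg_boxes = fg, mode = "tm", use_fg = TRUE,
                         seed = 1)
  expect_true(fit0$fg_regularized)
  expect_lt(grid_err(fit0$H), 1e-6)

  # matches confined to one small region overfit without regularization;
  # adding the box corners keeps the corner reprojection error small
  set.seed(10)
  local_m <- lapply(1:12, function(i) {
    v0 <- c(stats::runif(1, 60, 80), stats::runif(1, 40, 50))
    vel <- stats::runif(2, -1, 1)
    pv <- cbind(v0[1] + vel[1] * (0:9), v0[2] + vel[2] * (0:9))
    pu <- apply_homography(H_TEST, pv) + matrix(stats::rnorm(20, 0, 1), 10, 2)
    list(points_u = pu, points_v = pv)
  })
  fit_fg <- fit_homography(local_m, fg_boxes = fg, mode = "tm",
                           use_fg = TRUE, seed = 2)
  corner_err <- max(vapply(1:T, function(t)
    max(sqrt(rowSums((apply_homography(fit_fg$H, corners_v[[t]]) -
                        corners_u[[t]])^2))), numeric(1)))
  expect_lt(corner_err, 3)
})
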