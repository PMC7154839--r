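test_that("foreground edge extraction keeps silhouette points and prunes clutter", {
  s <- walk_scene()
  m <- s$masks[[1]]
  strength <- edge_strength(m * 1)
  # clutter far from the mask survives in the raw strength map but is
  # pruned by the distance-transform weight
  clutter <- strength
  clutter[2:3, 2:3] <- 1
  e <- extract_foreground_edges(clutter, m, seed = 1)
  expect_false(any(e$points[, 1] < 5 & e$points[, 2] < 5))
  expect_true(all(e$score > 0.2))
  expect_lte(nrow(e$points), 1000)

  # >= 90% of retained points lie within 2 px of the true silhouette
  segs <- s$skeleton[[1]]
  d <- apply(e$points, 1, function(p)
    min(vapply(segs, function(sg)
      abs(potkit:::point_segment(p[1], p[2], sg$a, sg$b)$dist - sg$radius),
      numeric(1))))
  expect_gte(mean(d <= 2), 0.9)

  # cap is enforced
  e2 <- extract_foreground_edges(clutter, m, max_points = 50, seed = 1)
  expect_lte(nrow(e2$points), 50)
  expect_error(extract_foreground_edges(strength, m & FALSE), "empty mask")
})

test_that("edge points propagate with the flow", {
  pts <- cbind(c(10, 20, 30), c(5, 6, 7))
  zero <- list(array(0, dim = c(50, 50, 2)))
  expect_equal(propagate_edges(pts, rep(zero, 4), 0, 3)$points, pts,
               ignore_attr = TRUE)
  unit <- array(0, dim = c(50, 50, 2)); unit[, , 1] <- 1
  pr <- propagate_edges(pts, rep(list(unit), 4), 0, 3)
  expect_equal(pr$points[, 1], pts[, 1] + 3)
  expect_equal(pr$points[, 2], pts[, 2])
  # backward propagation inverts the shift
  back <- propagate_edges(pr$points, rep(list(unit), 4), 3, 0)
  expect_equal(back$points, pts, ignore_attr = TRUE, tolerance = 1e-9)

  # on a synthetic scene, silhouette points track the analytic body motion
  s <- walk_scene()
  e <- extract_foreground_edges(edge_strength(s$masks[[1]] * 1), s$masks[[1]],
                                max_points = 400, seed = 2)
  pr9 <- propagate_edges(e$points, s$flow, 0, 9)
  segs <- s$skeleton[[1]]; seg9 <- s$skeleton[[10]]
  ana <- t(apply(e$points, 1, function(p) {
    k <- which.min(vapply(segs, function(sg)
      potkit:::point_segment(p[1], p[2], sg$a, sg$b)$dist - sg$radius,
      numeric(1)))
    sg <- segs[[k]]
    v <- sg$b - sg$a; len <- sqrt(sum(v * v))
    sr <- ((p[1] - sg$a[1]) * v[1] + (p[2] - sg$a[2]) * v[2]) / (len * len)
    off <- ((p[1] - sg$a[1]) * v[2] - (p[2] - sg$a[2]) * v[1]) / len
    potkit:::segment_local_to_world(seg9[[k]], sr, off)
  }))
  expect_lt(max(sqrt(rowSums((pr9$points - ana)^2))), 0.5)
})

test_that("TPS fitting interpolates, smooths to affine, and respects weights", {
  set.seed(3)
  V <- cbind(stats::runif(40), stats::runif(40))  # unit-box points
  A <- matrix(c(1.1, 0.1, -0.05, 0.95), 2, 2)
  U <- V %*% A + matrix(stats::rnorm(80, 0, 0.02), 40, 2)
  # lambda -> Inf: the warp vanishes and the fit matches affine regression
  f_inf <- fit_tps(U, V, lambda = 1e6)
  aff <- stats::lm.fit(cbind(1, V), U)$coefficients
  expect_lt(max(abs(tps_eval(f_inf, V) - cbind(1, V) %*% aff)), 1e-4)
  expect_lt(f_inf$bending, 1e-10)
  # lambda -> 0: interpolation at the control points (pixel scale, where
  # lambda = 1e-6 is negligible against the kernel)
  f0 <- fit_tps(U * 100, V * 100, lambda = 1e-6)
  expect_lt(max(abs(tps_eval(f0, V * 100) - U * 100)), 1e-6)
  # exactly affine pairs have zero bending at any lambda
  U2 <- V %*% A + matrix(c(0.05, -0.03), 40, 2, byrow = TRUE)
  f2 <- fit_tps(U2, V, lambda = 1)
  expect_lt(max(abs(tps_eval(f2, V) - U2)), 1e-8)
  expect_lt(f2$bending, 1e-12)
  # a heavily down-weighted pair barely moves the fit
  U3 <- U2; U3[1, ] <- U3[1, ] + 5
  f3 <- fit_tps(U3, V, lambda = 1e-3, weights = c(1e-9, rep(1, 39)))
  expect_lt(max(abs(tps_eval(f3, V[-1, , drop = FALSE]) -
                      U2[-1, , drop = FALSE])), 1e-2)
})

test_that("TPS-RPM has the identity fixed point and recovers warps under outliers", {
  set.seed(4)
  P <- cbind(stats::runif(60, 0, 100), stats::runif(60, 0, 100))
  r_id <- tps_rpm(P, P, T_final = 1)
  disp <- sqrt(rowSums((potkit:::tps_mapping_eval(r_id$mapping, P) - P)^2))
  expect_lt(mean(disp), 1e-3 * 100)

  for (sd in 1:3) {
    set.seed(sd)
    cs <- as.matrix(expand.grid(seq(10, 90, 40), seq(10, 90, 40)))
    cdst <- cs + matrix(stats::rnorm(nrow(cs) * 2, 0, 6), ncol = 2)
    w <- fit_tps(cdst, cs, lambda = 0)
    V <- cbind(stats::runif(80, 0, 100), stats::runif(80, 0, 100))
    U <- rbind(tps_eval(w, V),
               cbind(stats::runif(8, 0, 100), stats::runif(8, 0, 100)))
    r <- tps_rpm(U, V, T_final = 1)
    land <- cbind(stats::runif(30, 10, 90), stats::runif(30, 10, 90))
    err <- mean(sqrt(rowSums((potkit:::tps_mapping_eval(r$mapping, land) -
                                tps_eval(w, land))^2)))
    expect_lt(err / 100, 0.02)
  }
})

test_that("the annealing free energy never increases at a fixed temperature", {
  set.seed(5)
  cs <- as.matrix(expand.grid(seq(10, 90, 40), seq(10, 90, 40)))
  cdst <- cs + matrix(stats::rnorm(nrow(cs) * 2, 0, 6), ncol = 2)
  w <- fit_tps(cdst, cs, lambda = 0)
  V <- cbind(stats::runif(80, 0, 100), stats::runif(80, 0, 100))
  U <- rbind(tps_eval(w, V),
             cbind(stats::runif(8, 0, 100), stats::runif(8, 0, 100)))
  r <- tps_rpm(U, V, T_final = 1)
  tr <- r$energy_trace
  for (tmp in unique(tr[, 1])) {
    e <- tr[tr[, 1] == tmp, 2]
    expect_true(all(diff(e) <= 1e-9 * pmax(abs(e[-length(e)]), 1)))
  }
})

ttps_test_pair <- function() {
  cached("ttps_pair", {
    s1 <- make_scene(list(list(bp_walk(), 20)), image_size = c(96, 200),
                     n_traj = 80, seed = 11)
    set.seed(7)
    src <- as.matrix(expand.grid(seq(0, 199, 40), seq(0, 95, 31)))
    dst <- src + matrix(stats::rnorm(nrow(src) * 2, 0, 6), ncol = 2)
    s2 <- warp_scene(s1, mapping_tps(src, dst, lambda = 1e-4),
                     noise_px = 0, seed = 8)
    list(s1 = s1, s2 = s2, cmp = list(start_p = 5, start_q = 5, T = 10L))
  })
}

test_that("TTPS alignment of identical sequences is the identity with near-zero energy", {
  s <- walk_scene()
  cmp <- list(start_p = 3, start_q = 3, T = 6L)
  tt <- align_cmp_ttps(s, s, cmp, init_H = NULL, max_points = 80, seed = 1)
  # near-zero energy: the RMS residual implied by the mass-weighted data
  # term is a small fraction of a pixel
  rms <- sqrt(tt$energy / (cmp$T * sum(tt$M)))
  expect_lt(rms, 0.5)
  pts <- cbind(stats::runif(30, 60, 140), stats::runif(30, 30, 70))
  for (t in c(0, 3, 5)) {
    mapped <- apply_mapping(tt, pts, frame_t = t)
    expect_lt(mean(sqrt(rowSums((mapped - pts)^2))), 0.5)
  }
})

test_that("the returned TTPS candidate attains the minimum energy over anchors", {
  pair <- ttps_test_pair()
  hm <- align_cmp_homography(pair$s1, pair$s2, pair$cmp, mode = "tm",
                             use_fg = TRUE, seed = 1)
  tt <- align_cmp_ttps(pair$s1, pair$s2, pair$cmp, init_H = hm$H,
                       max_points = 120, seed = 1)
  expect_equal(tt$energy, min(tt$candidate_energies, na.rm = TRUE))
  expect_equal(length(tt$mappings), pair$cmp$T)
  expect_true(all(tt$M >= 0 & tt$M <= 1))
})

test_that("TTPS recovers a known scene warp at least as well as its homography init", {
  pair <- ttps_test_pair()
  hm <- align_cmp_homography(pair$s1, pair$s2, pair$cmp, mode = "tm",
                             use_fg = TRUE, seed = 1)
  tt <- align_cmp_ttps(pair$s1, pair$s2, pair$cmp, init_H = hm$H,
                       max_points = 250, seed = 1)
  # mean forward landmark error in pixels, relative to the scene diagonal
  px_err <- function(al) {
    tot <- c()
    for (t in 0:(pair$cmp$T - 1)) {
      l1 <- potkit:::cmp_landmarks(pair$s1, pair$cmp$start_p, pair$cmp$T)
      l2 <- potkit:::cmp_landmarks(pair$s2, pair$cmp$start_q, pair$cmp$T)
      l1 <- l1[l1$frame == t & l1$visible, ]
      l2 <- l2[l2$frame == t & l2$visible, ]
      common <- intersect(l1$name, l2$name)
      p1 <- as.matrix(l1[match(common, l1$name), c("x", "y")])
      p2 <- as.matrix(l2[match(common, l2$name), c("x", "y")])
      tot <- c(tot, sqrt(rowSums((apply_mapping(al, p2, frame_t = t) -
                                    p1)^2)))
    }
    mean(tot)
  }
  scene_diag <- sqrt(pair$s1$width^2 + pair$s1$height^2)
  e_h <- px_err(hm); e_t <- px_err(tt)
  expect_lte(e_t, e_h)
  expect_lt(e_t / scene_diag, 0.02)
})

test_that("mappings apply forward and invert numerically", {
  pair <- ttps_test_pair()
  hm <- align_cmp_homography(pair$s1, pair$s2, pair$cmp, mode = "tm",
                             use_fg = TRUE, seed = 1)
  pts <- cbind(stats::runif(25, 50, 150), stats::runif(25, 30, 70))
  # homography: forward equals the direct matrix product
  expect_equal(apply_mapping(hm, pts), apply_homography(hm$H, pts))
  expect_lt(max(abs(apply_mapping(hm, apply_mapping(hm, pts),
                                  direction = "reverse") - pts)), 1e-9)
  # TTPS: forward then reverse returns within 1% of the scene scale
  tt <- align_cmp_ttps(pair$s1, pair$s2, pair$cmp, init_H = hm$H,
                       max_points = 120, seed = 1)
  fwd <- apply_mapping(tt, pts, frame_t = 2)
  back <- apply_mapping(tt, fwd, frame_t = 2, direction = "reverse")
  scene_diag <- sqrt(pair$s1$width^2 + pair$s1$height^2)
  expect_lt(mean(sqrt(rowSums((back - pts)^2))) / scene_diag, 0.01)
})
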