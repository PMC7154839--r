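make_uniform_flow_frame <- function(h, w, u, v, mask) {
  fl <- array(0, dim = c(h, w, 2))
  fl[, , 1][mask] <- u
  fl[, , 2][mask] <- v
  fl
}

test_that("frame statistics match closed forms", {
  h <- 20; w <- 20
  mask <- matrix(FALSE, h, w); mask[5:16, 5:16] <- TRUE
  # uniform flow (3, 0): median (3, 0), sigma 0
  fl <- make_uniform_flow_frame(h, w, 3, 0, mask)
  st <- frame_stats(rep(list(fl), 10), rep(list(mask), 10), pot_config())
  expect_equal(st$v_m[1, ], c(3, 0))
  expect_equal(st$sigma[1], 0)
  expect_equal(st$s[1], 0)
  expect_true(st$pruned[1])

  # half the mask at speed 0, half at 2: mean 1, population sd 1, sigma 1
  mask2 <- matrix(FALSE, h, w); mask2[1:10, ] <- TRUE
  fl2 <- array(0, dim = c(h, w, 2))
  fl2[, , 1][1:5, ] <- 2
  st2 <- frame_stats(list(fl2), list(mask2), pot_config(n = 2))
  expect_equal(st2$sigma[1], 1)

  # empty mask: frame marked pruned
  st3 <- frame_stats(list(fl), list(matrix(FALSE, h, w)), pot_config(n = 2))
  expect_true(is.na(st3$sigma[1]))
  expect_true(st3$pruned[1])
})

test_that("pair scores have the closed form, symmetry and antisymmetry", {
  cfg <- pot_config(n = 10)
  # median velocity (1, 0) everywhere
  stats <- list(v_m = matrix(rep(c(1, 0), each = 12), 12, 2),
                sigma = rep(1, 12), s = rep(1, 12), pruned = rep(FALSE, 12))
  anchor <- line_traj(1, 0, c(10, 10), c(1, 0), 12)   # moves at the median
  swing <- line_traj(2, 0, c(30, 10), c(2, 0), 12)    # median + (1, 0)
  sc <- score_candidates(list(anchor, swing), stats, 0, cfg)
  expect_equal(nrow(sc), 2)
  s_as <- sc$score[sc$anchor_id == 1]
  expect_equal(s_as, 10)                        # n * 1
  expect_equal(sc$score[sc$anchor_id == 2], -10)  # antisymmetry
  # both at the median: zero score
  twin <- line_traj(3, 0, c(50, 30), c(1, 0), 12)
  sc2 <- score_candidates(list(anchor, twin), stats, 0, cfg)
  expect_equal(sc2$score, c(0, 0))
  # fewer than 2 live trajectories: empty
  expect_equal(nrow(score_candidates(list(anchor), stats, 0, cfg)), 0)
})

test_that("selection keeps the top fraction with lexicographic tie-breaks", {
  sc <- data.frame(anchor = 1:6, swing = c(2:6, 1),
                   anchor_id = c(5, 3, 1, 4, 2, 6),
                   swing_id = c(1, 2, 3, 4, 5, 6),
                   score = c(2, 2, 2, 1, 1, 0))
  all_kept <- select_pots(sc, pot_config(theta_P = 1))
  expect_equal(nrow(all_kept), 6)
  # theta_P = 0.5 keeps 3; ties at score 2 resolved by (anchor_id, swing_id)
  kept <- select_pots(sc, pot_config(theta_P = 0.5))
  expect_equal(nrow(kept), 3)
  expect_equal(kept$anchor_id, c(1, 3, 5))
  # brute-force comparison on random scores
  set.seed(8)
  sc2 <- data.frame(anchor = 1:40, swing = 40:1,
                    anchor_id = sample(40), swing_id = sample(40),
                    score = sample(stats::rnorm(8), 40, replace = TRUE))
  kept2 <- select_pots(sc2, pot_config(theta_P = 0.15))
  ord <- sc2[order(-sc2$score, sc2$anchor_id, sc2$swing_id), ]
  expect_equal(kept2, ord[1:ceiling(0.15 * 40), ])
})

test_that("the PoT descriptor has the documented closed form and invariances", {
  cfg <- pot_config(n = 10)
  anchor <- line_traj(1, 0, c(10, 10), c(0, 0), 10)
  swing <- line_traj(2, 0, c(10, 20), c(2, 0), 10)
  d <- pot_descriptor(anchor, swing, 0, cfg)
  expect_length(d, 19)
  expect_equal(d[1], atan2(10, 0))                # straight down in image coords
  expect_equal(d[-1], rep(c(1 / 9, 0), 9))        # D = 18, steps (2,0)/18

  # normalization: sum of step norms is 1
  norms <- sqrt(d[seq(2, 18, 2)]^2 + d[seq(3, 19, 2)]^2)
  expect_equal(sum(norms), 1, tolerance = 1e-12)

  # camera-pan invariance: add the same per-frame translation to both
  pan <- cbind(cumsum(stats::runif(10, -3, 3)), cumsum(stats::runif(10, -2, 2)))
  a2 <- anchor; a2$points <- a2$points + pan
  s2 <- swing; s2$points <- s2$points + pan
  expect_equal(pot_descriptor(a2, s2, 0, cfg), d, tolerance = 1e-12)

  # scale invariance
  a3 <- anchor; a3$points <- a3$points * 7
  s3 <- swing; s3$points <- s3$points * 7
  expect_equal(pot_descriptor(a3, s3, 0, cfg), d, tolerance = 1e-12)

  # rigid pair: D = 0 discards the PoT
  expect_null(pot_descriptor(anchor, line_traj(3, 0, c(40, 10), c(0, 0), 10),
                             0, cfg))
  # window not covered
  expect_error(pot_descriptor(line_traj(4, 5, c(1, 1), c(1, 0), 10), swing,
                              0, cfg), "window")
})

test_that("every extracted PoT is normalized and lies on the foreground", {
  s <- walk_scene()
  pots <- walk_pots()
  expect_equal(ncol(pots$descriptors), 19)
  step_norm <- function(d) sum(sqrt(d[seq(2, 18, 2)]^2 + d[seq(3, 19, 2)]^2))
  norms <- apply(pots$descriptors, 1, step_norm)
  expect_true(all(abs(norms - 1) < 1e-9))
  # anchors and swings are foreground trajectories at their start frame
  ids <- unique(c(pots$meta$anchor_id, pots$meta$swing_id))
  for (id in ids[1:20]) {
    tr <- s$trajectories[[id]]
    m <- s$masks[[1]]
    p <- tr$points[1, ]
    expect_true(m[round(p[2]) + 1, round(p[1]) + 1])
  }
})

test_that("swings concentrate on articulated parts in a walking scene", {
  s <- walk_scene()
  pots <- walk_pots()
  parts <- s$parts[pots$meta$swing_id]
  expect_gte(mean(grepl("leg|head|neck", parts)), 0.9)
})

test_that("pause scenes produce no PoTs and static frames are pruned", {
  s <- pause_scene()
  st <- frame_stats(s$flow, s$masks)
  expect_true(all(st$pruned))
  expect_equal(nrow(extract_pots(s, stats = st)$descriptors), 0)
  expect_error(extract_pots(list(trajectories = list(), masks = NULL,
                                 flow = NULL)), "masks and flow")
})

test_that("extraction equals the brute-force reference on a small scene", {
  s <- tiny_shot()
  cfg <- pot_config()
  got <- extract_pots(s, cfg)
  ref <- oracle_pots(s, cfg)
  expect_equal(nrow(got$descriptors), nrow(ref$descriptors))
  ord_g <- order(got$meta$start_frame, got$meta$anchor_id, got$meta$swing_id)
  ord_r <- order(ref$meta$start_frame, ref$meta$anchor_id, ref$meta$swing_id)
  expect_equal(got$meta$anchor_id[ord_g], ref$meta$anchor_id[ord_r])
  expect_equal(got$meta$swing_id[ord_g], ref$meta$swing_id[ord_r])
  expect_equal(got$meta$score[ord_g], ref$meta$score[ord_r], tolerance = 1e-10)
  expect_equal(got$descriptors[ord_g, ], ref$descriptors[ord_r, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})
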