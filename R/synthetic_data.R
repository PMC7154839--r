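#' Behavior programs for synthetic articulated scenes
#'
#' A behavior program drives the joint angles of the synthetic quadruped over
#' time. Periodic programs (gaits, head turning) use sinusoidal joint angle
#' functions with a fixed period in frames; `bp_pause()` freezes every joint
#' and the body translation, so foreground flow is identically zero;
#' `bp_sit()` ramps the hind-leg and pitch angles monotonically, giving
#' articulated but aperiodic motion.
#'
#' @param period gait period in frames (must be >= 5 for periodic programs)
#' @param speed forward translation of the torso in px/frame
#' @param amplitude leg swing amplitude about the vertical, radians
#' @param knee_amplitude lower-leg flexion amplitude, radians
#' @return an object of class `pot_behavior` with fields `name`, `period`
#'   (NA for aperiodic programs), `velocity` and `angles`, a function of the
#'   program-local frame index returning joint angles.
#' @name behavior_programs
NULL

new_behavior <- function(name, period, velocity, angles) {
  if (!is.na(period) && period < 5)
    stop("periodic programs require a period of at least 5 frames")
  structure(list(name = name, period = period, velocity = velocity,
                 angles = angles), class = "pot_behavior")
}

#' @rdname behavior_programs
#' @export
bp_walk <- function(period = 12, speed = 1, amplitude = 0.10,
                    knee_amplitude = 0.15) {
  ph <- c(0, 0.5, 1, 1.5) * pi  # lateral-sequence gait
  new_behavior("walk", period, speed, function(tau) {
    w <- 2 * pi * tau / period
    list(legs  = amplitude * sin(w + ph),
         knees = knee_amplitude * sin(w + ph + pi / 2),
         neck  = 0.05 * sin(w), head = 0, pitch = 0)
  })
}

#' @rdname behavior_programs
#' @export
bp_run <- function(period = 6, speed = 2, amplitude = 0.14,
                   knee_amplitude = 0.14) {
  b <- bp_walk(period, speed, amplitude, knee_amplitude)
  new_behavior("run", period, speed, b$angles)
}

#' @rdname behavior_programs
#' @export
bp_pause <- function() {
  new_behavior("pause", NA_real_, 0, function(tau) {
    list(legs = rep(0, 4), knees = rep(0, 4), neck = 0, head = 0, pitch = 0)
  })
}

#' @rdname behavior_programs
#' @export
bp_head_turn <- function(period = 10) {
  new_behavior("head_turn", period, 0, function(tau) {
    w <- 2 * pi * tau / period
    list(legs = rep(0, 4), knees = rep(0, 4),
         neck = 0.10 * sin(w), head = 0.35 * sin(w), pitch = 0)
  })
}

#' @rdname behavior_programs
#' @export
bp_sit <- function() {
  new_behavior("sit", NA_real_, 0, function(tau) {
    list(legs  = c(0, 0, -clamp(0.030 * tau, 0, 0.60), -clamp(0.030 * tau, 0, 0.60)),
         knees = c(0, 0, clamp(0.050 * tau, 0, 0.90), clamp(0.050 * tau, 0, 0.90)),
         neck = 0, head = 0, pitch = clamp(0.008 * tau, 0, 0.18))
  })
}

# ---------------------------------------------------------------------------
# Skeleton: 11 rigid capsules (torso, neck, head, 4 x two-segment legs) in a
# 2-D side view. Legs attach along the torso; angles are measured in the
# torso frame (legs from straight down, neck/head from the +x axis).
# ---------------------------------------------------------------------------

SKEL <- list(
  torso_half = 18, torso_r = 4,
  neck_len = 10, neck_r = 2.5, neck_angle = -0.65,
  head_len = 8, head_r = 3, head_angle = -0.15,
  leg_attach_x = c(15, 5, -5, -15), leg_attach_y = 2,
  leg_len = 10, leg_r = 2
)

# World-space segments at one frame. `angles` as returned by a program's
# angle function, `center` the torso center.
skeleton_segments <- function(center, angles) {
  psi <- angles$pitch
  R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
  tf <- function(v) center + as.numeric(R %*% v)  # torso frame -> world
  segs <- list()
  add <- function(name, group, a, b, r)
    segs[[length(segs) + 1L]] <<- list(name = name, group = group,
                                       a = a, b = b, radius = r)
  add("torso", "torso", tf(c(-SKEL$torso_half, 0)), tf(c(SKEL$torso_half, 0)),
      SKEL$torso_r)
  na <- SKEL$neck_angle + angles$neck
  nb <- c(SKEL$torso_half, 0)
  nt <- nb + SKEL$neck_len * c(cos(na), sin(na))
  add("neck", "neck", tf(nb), tf(nt), SKEL$neck_r)
  ha <- SKEL$head_angle + angles$neck + angles$head
  ht <- nt + SKEL$head_len * c(cos(ha), sin(ha))
  add("head", "head", tf(nt), tf(ht), SKEL$head_r)
  leg_names <- c("fl", "fr", "bl", "br")
  for (i in 1:4) {
    base <- c(SKEL$leg_attach_x[i], SKEL$leg_attach_y)
    a1 <- angles$legs[i]
    knee <- base + SKEL$leg_len * c(sin(a1), cos(a1))
    a2 <- a1 + angles$knees[i]
    tip <- knee + SKEL$leg_len * c(sin(a2), cos(a2))
    add(paste0("leg_", leg_names[i], "_upper"), "leg", tf(base), tf(knee),
        SKEL$leg_r)
    add(paste0("leg_", leg_names[i], "_lower"), "leg", tf(knee), tf(tip),
        SKEL$leg_r)
  }
  segs
}

# Raster quantities for one frame: foreground mask, per-pixel nearest segment
# and its local (s, off) coordinates (s unclamped so that a + s*v + off*n
# reconstructs the pixel exactly).
rasterize_frame <- function(segs, width, height) {
  px <- rep(0:(width - 1), each = height)
  py <- rep(0:(height - 1), times = width)
  n <- length(px)
  best <- rep(Inf, n); assign <- rep(NA_integer_, n)
  s_par <- numeric(n); o_par <- numeric(n)
  inside <- rep(FALSE, n)
  halo <- rep(FALSE, n)
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    v <- sg$b - sg$a
    len <- sqrt(sum(v * v))
    sr <- ((px - sg$a[1]) * v[1] + (py - sg$a[2]) * v[2]) / (len * len)
    off <- ((px - sg$a[1]) * v[2] - (py - sg$a[2]) * v[1]) / len
    cs <- clamp(sr, 0, 1)
    d <- sqrt((px - (sg$a[1] + cs * v[1]))^2 + (py - (sg$a[2] + cs * v[2]))^2)
    inside <- inside | (d <= sg$radius)
    halo <- halo | (d <= sg$radius + 2)
    score <- d - sg$radius  # signed distance to capsule surface
    upd <- score < best
    best[upd] <- score[upd]; assign[upd] <- k
    s_par[upd] <- sr[upd]; o_par[upd] <- off[upd]
  }
  # flow is defined on a 2 px halo around the body so that bilinear
  # interpolation at the silhouette never mixes in zero background flow
  list(mask = matrix(inside, height, width), halo = halo,
       assign = assign, s = s_par, off = o_par, px = px, py = py)
}

# Position of local coordinates (s, off) of segment `sg` in world space.
segment_local_to_world <- function(sg, s, off) {
  v <- sg$b - sg$a
  len <- sqrt(sum(v * v))
  nrm <- c(v[2], -v[1]) / len
  cbind(sg$a[1] + s * v[1] + off * nrm[1],
        sg$a[2] + s * v[2] + off * nrm[2])
}

#' Generate a synthetic articulated scene
#'
#' Renders a 2-D quadruped stick figure (11 rigid capsules) performing a
#' schedule of behavior programs into dense point trajectories, per-frame
#' binary foreground masks, per-frame dense optical flow, named landmarks and
#' per-frame behavior labels. The flow at every on-body pixel is the analytic
#' displacement of that body point between frames; trajectories are seeded on
#' the body segments and advected through the flow, so advecting a trajectory
#' point with the flow reproduces the next trajectory point exactly.
#'
#' @param schedule list of `list(program, duration)` entries, with `program`
#'   a [bp_walk()]-style behavior and `duration` in frames (>= 1)
#' @param image_size `c(height, width)` of the rendered frames in px
#' @param n_traj number of trajectories seeded at frame 0 (>= 50)
#' @param seed integer seed governing all sampling in the scene
#' @return an object of class `pot_scene` (also a `pot_shot`) with fields
#'   `frames`, `width`, `height`, `trajectories`, `parts` (body-part group of
#'   each trajectory), `masks`, `flow`, `landmarks`, `labels` and `skeleton`
#'   (per-frame segment list, the rendering ground truth).
#' @export
make_scene <- function(schedule, image_size = c(96, 224), n_traj = 120,
                       seed = 1) {
  stopifnot(length(schedule) >= 1, n_traj >= 50)
  height <- image_size[1]; width <- image_size[2]
  durations <- vapply(schedule, function(e) as.integer(e[[2]]), integer(1))
  if (any(durations < 1)) stop("all schedule durations must be >= 1")
  programs <- lapply(schedule, `[[`, 1)
  frames <- sum(durations)

  # per-frame program, local frame index, torso translation and labels
  prog_of <- rep(seq_along(programs), durations)
  tau_of <- unlist(lapply(durations, function(d) seq_len(d) - 1L))
  vel <- vapply(seq_len(frames),
                function(t) programs[[prog_of[t]]]$velocity, numeric(1))
  xoff <- cumsum(c(0, vel[-frames]))
  labels <- vapply(seq_len(frames),
                   function(t) programs[[prog_of[t]]]$name, character(1))

  cx0 <- 38; cy <- round(height * 0.48)
  skeleton <- vector("list", frames)
  for (t in seq_len(frames)) {
    ang <- programs[[prog_of[t]]]$angles(tau_of[t])
    segs <- skeleton_segments(c(cx0 + xoff[t], cy), ang)
    ends <- do.call(rbind, lapply(segs, function(s)
      rbind(s$a - s$radius, s$a + s$radius, s$b - s$radius, s$b + s$radius)))
    if (min(ends[, 1]) < 0 || max(ends[, 1]) > width - 1 ||
        min(ends[, 2]) < 0 || max(ends[, 2]) > height - 1)
      stop("skeleton leaves the image at frame ", t - 1L)
    skeleton[[t]] <- segs
  }

  masks <- vector("list", frames)
  flow <- vector("list", frames)
  rast <- vector("list", frames)
  for (t in seq_len(frames)) rast[[t]] <- rasterize_frame(skeleton[[t]],
                                                          width, height)
  for (t in seq_len(frames)) {
    masks[[t]] <- rast[[t]]$mask
    fl <- array(0, dim = c(height, width, 2))
    if (t < frames) {
      r <- rast[[t]]
      idx <- which(r$halo)
      if (length(idx)) {
        segs_now <- skeleton[[t]]; segs_nxt <- skeleton[[t + 1]]
        for (k in unique(r$assign[idx])) {
          sel <- idx[r$assign[idx] == k]
          # difference of two identically reconstructed positions, so a
          # static skeleton yields flow that is exactly zero
          now <- segment_local_to_world(segs_now[[k]], r$s[sel], r$off[sel])
          nxt <- segment_local_to_world(segs_nxt[[k]], r$s[sel], r$off[sel])
          u <- nxt[, 1] - now[, 1]; v <- nxt[, 2] - now[, 2]
          um <- matrix(0, height, width); vm <- matrix(0, height, width)
          um[sel] <- u; vm[sel] <- v
          fl[, , 1] <- fl[, , 1] + um; fl[, , 2] <- fl[, , 2] + vm
        }
      }
    }
    flow[[t]] <- fl
  }

  # trajectories: seeded on segment interiors at frame 0, advected by flow
  set.seed(seed)
  seg0 <- skeleton[[1]]
  seg_len <- vapply(seg0, function(s) sqrt(sum((s$b - s$a)^2)), numeric(1))
  seg_pick <- sample(seq_along(seg0), n_traj, replace = TRUE,
                     prob = seg_len)
  s0 <- stats::runif(n_traj, 0.15, 0.85)
  margin <- vapply(seg0[seg_pick], function(s) max(0, s$radius - 2), numeric(1))
  o0 <- stats::runif(n_traj, -1, 1) * margin
  pts <- matrix(0, n_traj, 2)
  for (i in seq_len(n_traj))
    pts[i, ] <- segment_local_to_world(seg0[[seg_pick[i]]], s0[i], o0[i])
  track <- array(0, dim = c(frames, n_traj, 2))
  track[1, , ] <- pts
  for (t in seq_len(frames - 1)) {
    d <- bilinear_flow(flow[[t]], track[t, , ])
    track[t + 1, , ] <- track[t, , ] + d
  }
  trajectories <- lapply(seq_len(n_traj), function(i)
    list(id = i, start = 0L, points = track[, i, , drop = TRUE]))
  parts <- vapply(seg0[seg_pick], `[[`, character(1), "name")

  landmarks <- do.call(rbind, lapply(seq_len(frames), function(t) {
    lm <- scene_landmarks(skeleton[[t]])
    data.frame(frame = t - 1L, name = lm$name, x = lm$x, y = lm$y,
               visible = lm$x >= 0 & lm$x <= width - 1 &
                 lm$y >= 0 & lm$y <= height - 1)
  }))

  structure(list(id = "scene", frames = frames, width = width,
                 height = height, trajectories = trajectories, parts = parts,
                 masks = masks, flow = flow, landmarks = landmarks,
                 labels = labels, skeleton = skeleton),
            class = c("pot_scene", "pot_shot"))
}

scene_landmarks <- function(segs) {
  by_name <- function(nm) segs[[which(vapply(segs, `[[`, character(1),
                                             "name") == nm)]]
  head <- by_name("head"); torso <- by_name("torso")
  out <- list(
    nose = head$b, eye = head$a + 0.6 * (head$b - head$a),
    neck = by_name("neck")$a, tail = torso$a
  )
  for (l in c("fl", "fr", "bl", "br")) {
    up <- by_name(paste0("leg_", l, "_upper"))
    lo <- by_name(paste0("leg_", l, "_lower"))
    out[[paste0("hip_", l)]] <- up$a
    out[[paste0("knee_", l)]] <- up$b
    out[[paste0("hoof_", l)]] <- lo$b
  }
  data.frame(name = names(out),
             x = vapply(out, `[`, numeric(1), 1),
             y = vapply(out, `[`, numeric(1), 2))
}

# ---------------------------------------------------------------------------
# Geometric mappings and warped scene copies
# ---------------------------------------------------------------------------

#' Degrade a synthetic scene's masks and flow
#'
#' Robustness knob for the otherwise exact scenes: erodes (negative) or
#' dilates (positive) every foreground mask by a disc of the given radius,
#' and adds i.i.d. Gaussian noise to the flow wherever it is defined.
#' Trajectories, landmarks and labels are untouched, so ground truth stays
#' valid while the inputs the pipeline sees become imperfect.
#'
#' @param scene a `pot_scene`
#' @param mask_px disc radius in px; negative erodes, positive dilates, 0
#'   leaves masks exact
#' @param flow_noise standard deviation of the flow noise in px/frame
#' @param seed noise seed
#' @return the degraded scene
#' @export
degrade_scene <- function(scene, mask_px = 0, flow_noise = 0, seed = 1) {
  out <- scene
  if (mask_px != 0) {
    brush <- EBImage::makeBrush(2 * abs(round(mask_px)) + 1, shape = "disc")
    op <- if (mask_px < 0) EBImage::erode else EBImage::dilate
    out$masks <- lapply(scene$masks, function(m)
      as.matrix(op(EBImage::Image(m * 1), brush)) > 0.5)
  }
  if (flow_noise > 0) {
    set.seed(seed)
    out$flow <- lapply(scene$flow, function(fl) {
      on <- fl[, , 1] != 0 | fl[, , 2] != 0
      fl[, , 1][on] <- fl[, , 1][on] + stats::rnorm(sum(on), 0, flow_noise)
      fl[, , 2][on] <- fl[, , 2][on] + stats::rnorm(sum(on), 0, flow_noise)
      fl
    })
  }
  out
}

#' Geometric mappings for scene warping
#'
#' `mapping_homography()` wraps a 3x3 homography matrix, and
#' `mapping_translation()` is a convenience for a pure translation.
#' `mapping_tps()` builds a thin-plate-spline mapping that carries the
#' `src` control points to `dst` (fitted with [fit_tps()]).
#' All mappings can be applied with [map_points()] and passed to
#' [warp_scene()].
#'
#' @param H a 3x3 invertible matrix
#' @param dx,dy translation in px
#' @param src,dst n x 2 control point matrices
#' @param lambda TPS smoothness weight
#' @return an object of class `pot_mapping`
#' @name mappings
NULL

#' @rdname mappings
#' @export
mapping_homography <- function(H) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  if (abs(det(H)) < 1e-12) stop("homography is not invertible")
  structure(list(type = "homography", H = H), class = "pot_mapping")
}

#' @rdname mappings
#' @export
mapping_translation <- function(dx, dy) {
  mapping_homography(matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3))
}

#' @rdname mappings
#' @export
mapping_tps <- function(src, dst, lambda = 0) {
  src <- as_pts(src); dst <- as_pts(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  structure(list(type = "tps", tps = fit_tps(dst, src, lambda = lambda)),
            class = "pot_mapping")
}

#' Apply a mapping to points
#' @param mapping a `pot_mapping`
#' @param pts n x 2 point matrix
#' @return mapped n x 2 matrix
#' @export
map_points <- function(mapping, pts) {
  pts <- as_pts(pts)
  if (mapping$type == "homography") apply_homography(mapping$H, pts)
  else tps_eval(mapping$tps, pts)
}

# Numeric inverse of a mapping over a pixel domain: a TPS fitted to swapped
# grid samples provides the initial guess, refined by fixed-point iteration
# x <- x + (p - phi(x)) (contractive for warps close to the identity).
mapping_inverse_fn <- function(mapping, width, height) {
  if (mapping$type == "homography") {
    Hi <- solve(mapping$H)
    return(function(p) apply_homography(Hi, p))
  }
  gx <- seq(0, width - 1, length.out = 24)
  gy <- seq(0, height - 1, length.out = 18)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  fg <- map_points(mapping, g)
  inv <- fit_tps(g, fg, lambda = 1e-8)
  function(p) {
    x <- tps_eval(inv, p)
    for (it in 1:8) x <- x + 0.8 * (p - map_points(mapping, x))
    x
  }
}

check_invertible <- function(mapping, width, height) {
  gx <- seq(1, width - 2, length.out = 12)
  gy <- seq(1, height - 2, length.out = 10)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  inv <- mapping_inverse_fn(mapping, width, height)
  back <- inv(map_points(mapping, g))
  if (max(abs(back - g)) > 0.5)
    stop("mapping is not invertible over the image domain")
  invisible(TRUE)
}

#' Warp a synthetic scene through a known mapping
#'
#' Produces a geometrically transformed copy of a scene: trajectories,
#' landmarks and masks are carried through the mapping (plus i.i.d. Gaussian
#' positional noise on trajectories and landmarks), and the flow field is
#' re-derived so that it remains consistent with the warped trajectories.
#' Labels and body-part assignments are preserved. Used to build alignment
#' test cases with a known ground-truth transformation.
#'
#' @param scene a `pot_scene`
#' @param mapping a `pot_mapping` (must be invertible over the image)
#' @param noise_px standard deviation of positional noise in px
#' @param seed seed for the noise
#' @return a new `pot_scene` of the same size
#' @export
warp_scene <- function(scene, mapping, noise_px = 0, seed = 1) {
  stopifnot(inherits(scene, "pot_scene"), inherits(mapping, "pot_mapping"))
  check_invertible(mapping, scene$width, scene$height)
  inv <- mapping_inverse_fn(mapping, scene$width, scene$height)
  set.seed(seed)
  out <- scene
  out$skeleton <- NULL

  noise <- function(n) if (noise_px > 0)
    matrix(stats::rnorm(2 * n, 0, noise_px), n, 2) else matrix(0, n, 2)

  out$trajectories <- lapply(scene$trajectories, function(tr) {
    p <- map_points(mapping, tr$points)
    tr$points <- p + noise(nrow(p))
    tr
  })
  lp <- map_points(mapping, cbind(scene$landmarks$x, scene$landmarks$y))
  lp <- lp + noise(nrow(lp))
  out$landmarks$x <- lp[, 1]; out$landmarks$y <- lp[, 2]
  out$landmarks$visible <- scene$landmarks$visible &
    lp[, 1] >= 0 & lp[, 1] <= scene$width - 1 &
    lp[, 2] >= 0 & lp[, 2] <= scene$height - 1

  # masks and flow are resampled on the fixed pixel grid via the inverse map
  px <- rep(0:(scene$width - 1), each = scene$height)
  py <- rep(0:(scene$height - 1), times = scene$width)
  src <- inv(cbind(px, py))
  inside <- src[, 1] >= 0 & src[, 1] <= scene$width - 1 &
    src[, 2] >= 0 & src[, 2] <= scene$height - 1
  for (t in seq_len(scene$frames)) {
    mv <- rep(0, length(px))
    mv[inside] <- bilinear_sample(scene$masks[[t]] * 1, src[inside, 1],
                                  src[inside, 2])
    out$masks[[t]] <- matrix(mv > 0.5, scene$height, scene$width)
    fl <- array(0, dim = c(scene$height, scene$width, 2))
    sel <- inside
    if (any(sel) && t < scene$frames) {
      d <- bilinear_flow(scene$flow[[t]], src[sel, , drop = FALSE])
      dst <- map_points(mapping, src[sel, , drop = FALSE] + d)
      u <- matrix(0, scene$height, scene$width); v <- u
      u[sel] <- dst[, 1] - px[sel]; v[sel] <- dst[, 2] - py[sel]
      fl[, , 1] <- u; fl[, , 2] <- v
    }
    out$flow[[t]] <- fl
  }
  out
}
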