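#' Gradient-magnitude edge strength
#'
#' Default edge-strength provider: central-difference gradient magnitude of
#' a grayscale image, normalized to `[0, 1]`. Any edge detector producing a
#' strength map in `[0, 1]` can be substituted.
#'
#' @param img numeric matrix
#' @return matrix of the same size in `[0, 1]`
#' @export
edge_strength <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  g <- sqrt(gx^2 + gy^2)
  mx <- max(g)
  if (mx > 0) g / mx else g
}

#' Extract foreground edge points
#'
#' Scores each pixel by its edge strength multiplied by a distance-transform
#' weight `exp(-DT / (0.1 * bbox diagonal))` with respect to the foreground
#' mask (weight 1 on the mask, decaying with distance), so background
#' clutter far from the object is removed while edges just outside an
#' imperfect mask survive. Points scoring at most 0.2 are pruned and the
#' rest uniformly subsampled to `max_points`.
#'
#' @param strength edge-strength map in `[0, 1]` (e.g. [edge_strength()])
#' @param mask foreground mask (nonempty)
#' @param max_points subsampling cap per frame
#' @param seed subsampling seed
#' @param prune score threshold below/at which points are dropped
#' @return a `pot_edges` list with `points` (n x 2) and `score`
#' @export
extract_foreground_edges <- function(strength, mask, max_points = 1000,
                                     seed = 1, prune = 0.2) {
  if (!any(mask)) stop("empty mask")
  dt <- as.matrix(EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))))
  wgt <- exp(-dt / (0.1 * bbox_diag(mask)))
  score <- strength * wgt
  idx <- which(score > prune)
  if (length(idx) > max_points) {
    set.seed(seed)
    idx <- sort(sample(idx, max_points))
  }
  structure(list(points = cbind(x = (idx - 1) %/% nrow(mask),
                                y = (idx - 1) %% nrow(mask)),
                 score = score[idx]), class = "pot_edges")
}

#' Propagate edge points with optical flow
#'
#' Advects points frame by frame with bilinearly sampled flow, forward
#' (`to_t > from_t`) or backward (approximate inverse advection). Point
#' index identity is preserved; points leaving the image are marked and
#' should be retired from all frames by the caller.
#'
#' @param points n x 2 matrix at frame `from_t`
#' @param flow list of per-frame flow arrays (`flow[[t+1]]` maps frame t to
#'   t+1, 0-based)
#' @param from_t,to_t 0-based frame indices
#' @return list with `points` (n x 2) and logical `ok` (stayed inside)
#' @export
propagate_edges <- function(points, flow, from_t, to_t) {
  p <- as_pts(points)
  h <- dim(flow[[1]])[1]; w <- dim(flow[[1]])[2]
  ok <- rep(TRUE, nrow(p))
  if (to_t > from_t) {
    for (t in from_t:(to_t - 1)) p <- p + bilinear_flow(flow[[fr(t)]], p)
  } else if (to_t < from_t) {
    for (t in (from_t - 1):to_t) p <- p - bilinear_flow(flow[[fr(t)]], p)
  }
  ok <- p[, 1] >= 0 & p[, 1] <= w - 1 & p[, 2] >= 0 & p[, 2] <= h - 1
  list(points = p, ok = ok)
}

# ---------------------------------------------------------------------------
# Thin-plate splines
# ---------------------------------------------------------------------------

# Greedy minimum-spacing thinning in index order (deterministic).
thin_points <- function(p, dmin) {
  p <- as_pts(p)
  if (nrow(p) < 2) return(p)
  keep <- 1L
  for (i in 2:nrow(p)) {
    d2 <- (p[keep, 1] - p[i, 1])^2 + (p[keep, 2] - p[i, 2])^2
    if (min(d2) >= dmin * dmin) keep <- c(keep, i)
  }
  p[keep, , drop = FALSE]
}

tps_kernel <- function(r) {
  k <- r * r * log(r)
  k[!is.finite(k)] <- 0
  k
}

cross_dist <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rep(1, nrow(b))) - 2 * a %*% t(b) +
              outer(rep(1, nrow(a)), rowSums(b^2)), 0))
}

#' Fit a thin-plate spline to point pairs
#'
#' Finds the TPS `f` (affine part plus radial warp on the control points)
#' minimizing `sum_i w_i ||u_i - f(v_i)||^2 + lambda * L(f)` with `L` the
#' bending energy (integral of squared second derivatives), in closed form.
#' As `lambda -> Inf` the warp vanishes and the fit tends to the
#' least-squares affine map; as `lambda -> 0` it interpolates the points.
#'
#' @param U n x 2 target points
#' @param V_points n x 2 source/control points (>= 3, not all collinear)
#' @param lambda smoothness weight (>= 0)
#' @param weights optional per-pair nonnegative weights
#' @return a `pot_tps` with affine part `d` (3 x 2), warp coefficients `w`
#'   (n x 2), `control`, `lambda` and `bending` energy
#' @export
fit_tps <- function(U, V_points, lambda = 0, weights = NULL) {
  U <- as_pts(U); V_points <- as_pts(V_points)
  n <- nrow(V_points)
  stopifnot(nrow(U) == n, n >= 3)
  wts <- weights %||% rep(1, n)
  wts <- pmax(wts, 1e-12)  # floor only to avoid Inf; a vanishing weight
                           # effectively removes the pair from the fit
  K <- tps_kernel(cross_dist(V_points, V_points))
  P <- cbind(1, V_points)
  A <- rbind(cbind(K + lambda * diag(1 / wts, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(U, matrix(0, 3, 2))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("singular TPS system; using regularized solve")
    solve(A + diag(1e-8, nrow(A)), rhs)
  })
  w <- sol[seq_len(n), , drop = FALSE]
  d <- sol[(n + 1):(n + 3), , drop = FALSE]
  structure(list(control = V_points, w = w, d = d, lambda = lambda,
                 bending = sum(diag(t(w) %*% K %*% w))),
            class = "pot_tps")
}

#' Evaluate a thin-plate spline
#' @param tps a `pot_tps`
#' @param pts n x 2 points
#' @return mapped n x 2 points
#' @export
tps_eval <- function(tps, pts) {
  pts <- as_pts(pts)
  cbind(1, pts) %*% tps$d + tps_kernel(cross_dist(pts, tps$control)) %*% tps$w
}

# Composite mapping: optional pre-warp (homography) followed by a TPS.
tps_mapping_eval <- function(m, pts) {
  pts <- as_pts(pts)
  if (!is.null(m$pre)) pts <- apply_homography(m$pre, pts)
  tps_eval(m$tps, pts)
}

#' Robust point matching with deterministic annealing (TPS-RPM)
#'
#' Jointly estimates a TPS mapping `f` (applied to V, targeting U) and a
#' soft correspondence matrix M by alternating a correspondence update
#' (Gaussian affinities of the current residuals with an outlier row and
#' column, balanced by iterative row/column scaling) and a weighted TPS fit
#' to the M-averaged targets, while the temperature anneals geometrically.
#' The smoothness weight is tied to the temperature
#' (`lambda = lambda0 * temperature`). The alternation objective tracked in
#' `energy_trace` is the annealing free energy (the soft-assignment data
#' term plus bending energy plus the temperature-weighted entropy), which is
#' non-increasing across alternations at a fixed temperature.
#'
#' @param U n x 2 target point set
#' @param V_points k x 2 source point set
#' @param init optional 3 x 3 homography pre-applied to `V_points`
#'   (composed into the returned mapping)
#' @param lambda0 smoothness scale
#' @param anneal annealing rate in (0, 1)
#' @param inner alternations per temperature
#' @param T_init initial temperature (mean squared nearest-neighbor
#'   distance by default)
#' @param T_final final temperature in px^2
#' @param sinkhorn row/column balancing iterations
#' @return list with `mapping` (evaluable with [apply_mapping()]), `M`
#'   (n x k soft correspondences), `energy_trace` (one row per alternation:
#'   temperature, free energy) and `converged`
#' @export
tps_rpm <- function(U, V_points, init = NULL, lambda0 = 1, anneal = 0.93,
                    inner = 5, T_init = NULL, T_final = 1, sinkhorn = 30) {
  U <- as_pts(U); V0 <- as_pts(V_points)
  stopifnot(nrow(U) >= 3, nrow(V0) >= 3)
  V <- if (!is.null(init)) apply_homography(init, V0) else V0
  n <- nrow(U); k <- nrow(V)
  f <- fit_tps(V, V, lambda = 1e-6)  # identity initialization
  if (is.null(T_init)) {
    d <- cross_dist(U, V)
    T_init <- max(mean(apply(d, 1, min)^2), T_final)
  }
  temp <- T_init
  trace <- NULL
  M <- NULL
  while (temp >= T_final * (1 - 1e-9)) {
    for (it in seq_len(inner)) {
      fv <- tps_eval(f, V)
      d2 <- cross_dist(U, fv)^2
      # soft-assign with outlier row/column, balanced by Sinkhorn scaling
      A <- exp(-d2 / (2 * temp))
      A <- rbind(cbind(A, exp(-0.5)), c(rep(exp(-0.5), k), 0))
      for (s in seq_len(sinkhorn)) {
        rs <- rowSums(A[seq_len(n), , drop = FALSE])
        A[seq_len(n), ] <- A[seq_len(n), ] / pmax(rs, 1e-300)
        cs <- colSums(A[, seq_len(k), drop = FALSE])
        A[, seq_len(k)] <- t(t(A[, seq_len(k)]) / pmax(cs, 1e-300))
      }
      M <- A[seq_len(n), seq_len(k), drop = FALSE]
      mj <- colSums(M)
      Y <- (t(M) %*% U) / pmax(mj, 1e-12)
      lam <- lambda0 * temp
      f <- fit_tps(Y, V, lambda = lam, weights = mj)
      # annealing free energy: data term, outlier cost (the exp(-1/2)
      # affinity corresponds to a squared distance of `temp`), bending, and
      # the entropic term m (log m - 1) of the full balanced matrix, whose
      # KKT point is exactly the row/column-scaled soft-assign update
      ent <- function(m) sum(m * (log(pmax(m, 1e-300)) - 1))
      out_col <- A[seq_len(n), k + 1]; out_row <- A[n + 1, seq_len(k)]
      fe <- sum(M * cross_dist(U, tps_eval(f, V))^2) +
        temp * (sum(out_col) + sum(out_row)) + lam * f$bending +
        2 * temp * (ent(M) + ent(out_col) + ent(out_row))
      trace <- rbind(trace, c(temperature = temp, energy = fe))
    }
    if (temp == T_final) break
    temp <- max(temp * anneal, T_final)
  }
  mapping <- structure(list(pre = init, tps = f), class = "pot_tps_map")
  list(mapping = mapping, M = M, energy_trace = trace, converged = TRUE)
}

#' Temporal thin-plate-spline alignment of a CMP
#'
#' Fits one TPS per frame under the temporal constraint that all frames
#' share a single correspondence matrix: for each anchor frame `tau`,
#' TPS-RPM is run on the edge points extracted at `tau` (initialized with
#' the homography), the resulting correspondences are frozen and carried to
#' every other frame by optical-flow propagation of both point sets, and a
#' per-frame TPS is fitted to the propagated pairs. This yields T candidate
#' alignments; the one with the lowest total energy (summed weighted
#' residuals plus bending over all frames) is returned.
#'
#' @param edges_u,edges_v lists of T `pot_edges` (one per CMP frame) for
#'   the two sequences
#' @param flow_u,flow_v per-frame flow lists covering the CMP windows
#'   (relative frames, `flow[[t+1]]` maps t to t+1)
#' @param init_H homography initialization (3 x 3), or NULL
#' @param lambda0,anneal,inner,T_final TPS-RPM parameters
#' @param max_points per-frame cap on edge points used (subsampled by
#'   `seed`)
#' @param seed subsampling seed
#' @return a `pot_ttps`: list with `tau` (chosen anchor frame, 0-based),
#'   `mappings` (per-frame, applied with [apply_mapping()]), `M`,
#'   `energy`, `candidate_energies`, or NULL when every candidate fails
#' @export
fit_ttps <- function(edges_u, edges_v, flow_u, flow_v, init_H = NULL,
                     lambda0 = 1, anneal = 0.93, inner = 5, T_final = 1,
                     max_points = 300, seed = 1) {
  T_len <- length(edges_u)
  stopifnot(length(edges_v) == T_len, T_len >= 1)
  cap <- function(e, s) {
    # thin to a 2 px minimum spacing first: the final annealing temperature
    # (1 px^2) can only resolve individual correspondences when neighboring
    # samples are farther apart than a few standard deviations, and edge maps
    # deliver bands of directly adjacent pixels
    p <- thin_points(e$points, 3)
    if (nrow(p) > max_points) {
      set.seed(s)
      p <- p[sort(sample(nrow(p), max_points)), , drop = FALSE]
    }
    p
  }
  best <- NULL
  energies <- rep(NA_real_, T_len)
  for (tau in 0:(T_len - 1)) {
    # one seed per anchor frame for both sequences, so identical inputs
    # subsample to identical point sets (exact fixed point of the matcher)
    Pu <- cap(edges_u[[tau + 1]], seed + tau)
    Pv <- cap(edges_v[[tau + 1]], seed + tau)
    if (nrow(Pu) < 3 || nrow(Pv) < 3) next
    rpm <- tps_rpm(Pu, Pv, init = init_H, lambda0 = lambda0,
                   anneal = anneal, inner = inner, T_final = T_final)
    # propagate both sets to every frame; retire points that leave the image
    prop_u <- vector("list", T_len); prop_v <- vector("list", T_len)
    ok_u <- rep(TRUE, nrow(Pu)); ok_v <- rep(TRUE, nrow(Pv))
    for (t in 0:(T_len - 1)) {
      pu <- propagate_edges(Pu, flow_u, tau, t)
      pv <- propagate_edges(Pv, flow_v, tau, t)
      prop_u[[t + 1]] <- pu$points; prop_v[[t + 1]] <- pv$points
      ok_u <- ok_u & pu$ok; ok_v <- ok_v & pv$ok
    }
    if (sum(ok_u) < 3 || sum(ok_v) < 3) next
    M <- rpm$M[ok_u, ok_v, drop = FALSE]
    mj <- colSums(M)
    lam <- lambda0 * T_final
    mappings <- vector("list", T_len)
    energy <- 0
    for (t in 0:(T_len - 1)) {
      Ut <- prop_u[[t + 1]][ok_u, , drop = FALSE]
      Vt <- prop_v[[t + 1]][ok_v, , drop = FALSE]
      Vw <- if (!is.null(init_H)) apply_homography(init_H, Vt) else Vt
      Y <- (t(M) %*% Ut) / pmax(mj, 1e-12)
      ft <- fit_tps(Y, Vw, lambda = lam, weights = mj)
      mappings[[t + 1]] <- structure(list(pre = init_H, tps = ft,
                                          control_raw = Vt),
                                     class = "pot_tps_map")
      energy <- energy +
        sum(M * cross_dist(Ut, tps_eval(ft, Vw))^2) + lam * ft$bending
    }
    energies[tau + 1] <- energy
    if (is.null(best) || energy < best$energy)
      best <- list(tau = tau, mappings = mappings, M = M, energy = energy)
  }
  if (is.null(best)) return(NULL)
  structure(c(best, list(candidate_energies = energies)),
            class = "pot_ttps")
}

#' Apply an alignment mapping to points
#'
#' Forward maps second-sequence coordinates into the first sequence
#' (`u = f(v)`); `"reverse"` applies the inverse (exact for homographies,
#' numeric for TPS mappings via a grid-fitted inverse spline).
#'
#' @param alignment a `pot_homography` or `pot_ttps`
#' @param points n x 2 points
#' @param frame_t 0-based CMP frame (TTPS only)
#' @param direction `"forward"` or `"reverse"`
#' @return mapped n x 2 points
#' @export
apply_mapping <- function(alignment, points,
                          frame_t = 0, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  points <- as_pts(points)
  if (inherits(alignment, "pot_homography")) {
    H <- if (direction == "forward") alignment$H else solve(alignment$H)
    return(apply_homography(H, points))
  }
  if (inherits(alignment, "pot_ttps")) {
    m <- alignment$mappings[[frame_t + 1]]
    if (direction == "forward") return(tps_mapping_eval(m, points))
    # numeric inverse: a spline fitted from the forward-mapped control
    # points back to their sources gives the initial guess (clamped to the
    # control domain, where the spline is trustworthy), refined by damped
    # Gauss-Newton with a finite-difference Jacobian
    src <- m$control_raw
    fwd <- tps_mapping_eval(m, src)
    inv0 <- fit_tps(src, fwd, lambda = 1e-4)
    x <- tps_eval(inv0, points)
    pad <- 10
    x[, 1] <- clamp(x[, 1], min(src[, 1]) - pad, max(src[, 1]) + pad)
    x[, 2] <- clamp(x[, 2], min(src[, 2]) - pad, max(src[, 2]) + pad)
    h <- 0.5
    for (it in 1:12) {
      r <- tps_mapping_eval(m, x) - points
      jx <- (tps_mapping_eval(m, cbind(x[, 1] + h, x[, 2])) - r - points) / h
      jy <- (tps_mapping_eval(m, cbind(x[, 1], x[, 2] + h)) - r - points) / h
      det <- jx[, 1] * jy[, 2] - jy[, 1] * jx[, 2]
      det[abs(det) < 1e-9] <- 1e-9
      dx <- (r[, 1] * jy[, 2] - r[, 2] * jy[, 1]) / det
      dy <- (r[, 2] * jx[, 1] - r[, 1] * jx[, 2]) / det
      step <- cbind(dx, dy)
      nrm <- sqrt(rowSums(step^2))
      over <- nrm > 20  # clamp runaway steps outside the trust region
      step[over, ] <- step[over, ] * (20 / nrm[over])
      x_new <- x - step
      r_new <- tps_mapping_eval(m, x_new) - points
      worse <- rowSums(r_new^2) > rowSums(r^2)
      x_new[worse, ] <- x[worse, ] - 0.3 * step[worse, , drop = FALSE]
      x <- x_new
    }
    return(x)
  }
  stop("unsupported alignment object")
}
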