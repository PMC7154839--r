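# Self-contained brute-force reference for the full PoT extraction,
# independent of the package's vectorized implementation. Plain loops,
# direct formula transcription.

oracle_pots <- function(shot, config) {
  n <- config$n
  masks <- shot$masks
  # foreground trajectories: every point inside the mask of its frame
  on_fg <- function(tr) {
    for (k in seq_len(nrow(tr$points))) {
      m <- masks[[tr$start + k]]
      x <- round(tr$points[k, 1]) + 1
      y <- round(tr$points[k, 2]) + 1
      if (x < 1 || x > ncol(m) || y < 1 || y > nrow(m) || !m[y, x])
        return(FALSE)
    }
    TRUE
  }
  trajs <- Filter(on_fg, shot$trajectories)

  # frame statistics
  nf <- length(masks)
  sigma <- rep(NA_real_, nf)
  vmx <- rep(NA_real_, nf); vmy <- rep(NA_real_, nf)
  for (t in seq_len(nf)) {
    sel <- which(masks[[t]])
    if (!length(sel)) next
    u <- shot$flow[[t]][, , 1][sel]; v <- shot$flow[[t]][, , 2][sel]
    vmx[t] <- stats::median(u); vmy[t] <- stats::median(v)
    mag <- sqrt(u^2 + v^2)
    mu <- mean(mag)
    sigma[t] <- if (mu < 1e-6) 0 else sqrt(mean((mag - mu)^2)) / mu
  }

  alive <- function(tr, f) tr$start <= f && tr$start + nrow(tr$points) - 1 >= f

  out_desc <- NULL; out_meta <- NULL
  for (f in 0:(nf - 1)) {
    if (f + n - 1 > nf - 1) next
    win <- sigma[(f + 1):(f + n)]
    if (anyNA(win) || mean(win) < config$theta_F) next
    live <- Filter(function(tr) alive(tr, f) && alive(tr, f + n - 1), trajs)
    if (length(live) < 2) next
    rows <- NULL
    for (a in seq_along(live)) for (s in seq_along(live)) {
      if (a == s) next
      S <- 0
      for (k in f:(f + n - 1)) {
        vm <- c(vmx[k + 1], vmy[k + 1])
        # per-frame displacement, the last one reused for the window end
        last_in <- f + n - 2
        ia <- min(k, last_in) - live[[a]]$start + 1
        is <- min(k, last_in) - live[[s]]$start + 1
        va <- live[[a]]$points[ia + 1, ] - live[[a]]$points[ia, ] - vm
        vs <- live[[s]]$points[is + 1, ] - live[[s]]$points[is, ] - vm
        S <- S + sqrt(sum(vs^2)) - sqrt(sum(va^2))
      }
      rows <- rbind(rows, data.frame(a = a, s = s,
                                     aid = live[[a]]$id, sid = live[[s]]$id,
                                     S = S))
    }
    keep <- ceiling(config$theta_P * nrow(rows))
    rows <- rows[order(-rows$S, rows$aid, rows$sid), ][seq_len(keep), ]
    for (r in seq_len(nrow(rows))) {
      ta <- live[[rows$a[r]]]; ts <- live[[rows$s[r]]]
      ia <- (f - ta$start + 1):(f - ta$start + n)
      is <- (f - ts$start + 1):(f - ts$start + n)
      rel <- ts$points[is, ] - ta$points[ia, ]
      d <- rel[-1, , drop = FALSE] - rel[-n, , drop = FALSE]
      D <- sum(sqrt(rowSums(d^2)))
      if (D == 0) next
      desc <- c(atan2(rel[1, 2], rel[1, 1]), as.vector(t(d / D)))
      out_desc <- rbind(out_desc, desc)
      out_meta <- rbind(out_meta, data.frame(anchor_id = rows$aid[r],
                                             swing_id = rows$sid[r],
                                             start_frame = f,
                                             score = rows$S[r]))
    }
  }
  list(descriptors = unname(out_desc), meta = out_meta)
}
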