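#' Temporal partitioning configuration
#'
#' @param theta_H minimum normalized FFT peak height for a window to count
#'   as periodic
#' @param min_pause minimum length of a pause, in frames
#' @param window_stride stride of the sliding-window start positions, in
#'   frames
#' @param min_window smallest window length searched. The hard floor is 15
#'   frames (period >= 5 times frequency >= 3); the default is higher
#'   because with only a handful of admissible frequency bins the maximum
#'   bin of even a featureless spectrum approaches the detection threshold,
#'   so very short windows cannot give a calibrated peak height.
#' @return a `partition_config` list
#' @export
partition_config <- function(theta_H = 0.1, min_pause = 3, window_stride = 5,
                             min_window = 40) {
  stopifnot(theta_H > 0, theta_H < 1, min_pause >= 1, window_stride >= 1,
            min_window >= 15)
  structure(list(theta_H = theta_H, min_pause = as.integer(min_pause),
                 window_stride = as.integer(window_stride),
                 min_window = as.integer(min_window)),
            class = "partition_config")
}

#' Detect pauses
#'
#' Pauses are maximal runs of at least `min_pause` consecutive frames whose
#' normalized flow spread `sigma` is below the frame-pruning threshold
#' `theta_F`, i.e. frames without articulated object motion.
#'
#' @param stats a [frame_stats()] result
#' @param config a [partition_config()]
#' @param theta_F articulation threshold (defaults to the PoT pruning value)
#' @param shot_id identifier for the returned intervals
#' @return list of pause intervals
#' @export
detect_pauses <- function(stats, config = partition_config(),
                          theta_F = 0.1, shot_id = "shot") {
  still <- !is.na(stats$sigma) & stats$sigma < theta_F
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= config$min_pause)
      out[[length(out) + 1L]] <- interval(shot_id, starts[k] - 1L, ends[k])
  }
  out
}

#' Framewise bag-of-words matrix
#'
#' Assigns every PoT to its start frame and counts codeword occurrences,
#' giving the V x frames matrix whose rows are the codeword time series used
#' by the periodicity analysis.
#'
#' @param pots a `pot_set` from [extract_pots()]
#' @param codebook a [build_codebook()] result
#' @param frames number of frames in the shot
#' @return V x frames count matrix
#' @export
framewise_bow <- function(pots, codebook, frames) {
  V <- nrow(codebook$centroids)
  out <- matrix(0, V, frames)
  if (nrow(pots$descriptors) == 0) return(out)
  words <- assign_codewords(pots$descriptors, codebook)
  f <- pots$meta$start_frame + 1L
  for (i in seq_along(words)) out[words[i], f[i]] <- out[words[i], f[i]] + 1
  out
}

#' Summed FFT periodicity spectrum of a codeword-series window
#'
#' Transforms each codeword time series with the FFT and sums the power
#' (squared-magnitude) spectra over codewords, so peaks arise only when
#' several codewords recur with the same frequency. The DC component is
#' dropped and the remaining spectrum normalized so the total energy
#' integrates to 1; the peak is the highest bin among frequencies with at
#' least 3 cycles in the window and a period of at least 5 frames. Summing
#' power rather than raw magnitudes concentrates genuinely periodic energy
#' quadratically in its frequency bin while a broadband baseline stays
#' flat, which is what makes a single threshold on the peak height usable.
#'
#' @param bow_window V x L matrix (L >= 15)
#' @return list with `spectrum` (normalized non-DC energies, length
#'   floor(L/2)), `peak_height`, `frequency` (cycles in the window) and
#'   `period` (frames); peak fields are 0/NA when no admissible bin has
#'   energy
#' @export
periodicity_spectrum <- function(bow_window) {
  L <- ncol(bow_window)
  if (L < 15) stop("periodicity window must be at least 15 frames")
  nb <- floor(L / 2)
  spec <- rep(0, nb)
  for (i in seq_len(nrow(bow_window))) {
    x <- bow_window[i, ]
    if (all(x == x[1])) next  # constant series: no non-DC energy
    spec <- spec + Mod(stats::fft(x))[2:(nb + 1)]^2
  }
  tot <- sum(spec)
  if (tot > 0) spec <- spec / tot
  admissible <- which(seq_len(nb) >= 3 & L / seq_len(nb) >= 5)
  if (!length(admissible) || tot == 0)
    return(list(spectrum = spec, peak_height = 0, frequency = NA_integer_,
                period = NA_real_))
  k <- admissible[which.max(spec[admissible])]
  list(spectrum = spec, peak_height = spec[k], frequency = k,
       period = L / k)
}

#' Greedy recursive search for periodic sub-intervals
#'
#' Slides windows of every length from `min_window` up to the segment
#' length over the interval (start positions on a `window_stride` grid,
#' plus the flush-right position so boundaries at the segment end are
#' reachable), labels the window with the highest admissible FFT peak as
#' periodic when the peak reaches `theta_H`, and reprocesses the remaining
#' segments (which may contain motion with different periods) until no
#' window qualifies. Returned windows are disjoint.
#'
#' @param iv an [interval()] to search
#' @param bow V x frames matrix for the whole shot ([framewise_bow()])
#' @param config a [partition_config()]
#' @return list of `list(window = interval, result = periodicity result)`
#' @export
find_periodic_subintervals <- function(iv, bow, config = partition_config()) {
  out <- list()
  recurse <- function(a, b) {  # half-open [a, b)
    len <- b - a
    if (len < config$min_window) return()
    best <- NULL
    for (L in config$min_window:len) {
      starts <- unique(c(seq(a, b - L, by = config$window_stride), b - L))
      for (w0 in starts) {
        r <- periodicity_spectrum(bow[, (w0 + 1):(w0 + L), drop = FALSE])
        if (is.null(best) || r$peak_height > best$result$peak_height)
          best <- list(window = interval(iv$shot_id, w0, w0 + L), result = r)
      }
    }
    if (is.null(best) || best$result$peak_height < config$theta_H) return()
    out[[length(out) + 1L]] <<- best
    recurse(a, best$window$start)
    recurse(best$window$end, b)
  }
  recurse(iv$start, iv$end)
  out[order(vapply(out, function(x) x$window$start, numeric(1)))]
}

#' Partition a shot into single-behavior intervals
#'
#' Cuts at pauses first (pause frames are dropped: they carry no articulated
#' motion by definition), then refines each remaining segment by periodic
#' windows. Leftover frames between periodic windows form their own
#' non-periodic intervals; leftovers shorter than 2 frames are merged into
#' the adjacent interval so no returned interval is shorter than 2 frames.
#'
#' @param shot a `pot_shot`
#' @param pots a `pot_set` for the shot
#' @param stats a [frame_stats()] result
#' @param config a [partition_config()]
#' @param codebook optional codebook for the framewise BoW; by default a
#'   small codebook (V <= 50) is built from the shot's own PoTs
#' @param theta_F articulation threshold used for pause detection
#' @return list of disjoint intervals covering all non-pause frames
#' @export
partition_shot <- function(shot, pots, stats, config = partition_config(),
                           codebook = NULL, theta_F = 0.1) {
  frames <- shot$frames
  pauses <- detect_pauses(stats, config, theta_F, shot_id = shot$id)
  in_pause <- rep(FALSE, frames)
  for (p in pauses) in_pause[(p$start + 1):p$end] <- TRUE

  nd <- nrow(pots$descriptors)
  bow <- NULL
  if (nd >= 4) {
    if (is.null(codebook))
      codebook <- build_codebook(pots$descriptors,
                                 V = max(2, min(50, floor(nd / 4))),
                                 restarts = 2, seed = 7)
    bow <- framewise_bow(pots, codebook, frames)
  }

  segments <- runs_of(!in_pause)
  out <- list()
  for (sg in segments) {
    a <- sg[1]; b <- sg[2]  # half-open 0-based
    if (b - a < 2) next     # nothing articulated to report here
    periodic <- if (!is.null(bow))
      find_periodic_subintervals(interval(shot$id, a, b), bow, config)
    else list()
    per_bounds <- lapply(periodic, function(x) c(x$window$start,
                                                 x$window$end))
    bounds <- sort(unique(c(a, unlist(per_bounds), b)))
    pieces <- cbind(bounds[-length(bounds)], bounds[-1])
    pieces <- pieces[pieces[, 2] - pieces[, 1] > 0, , drop = FALSE]
    is_per <- apply(pieces, 1, function(p) any(vapply(per_bounds, function(w)
      w[1] == p[1] && w[2] == p[2], logical(1))))
    # leftover pieces too short to ever certify as a distinct behavior
    # (shorter than the 15-frame periodicity floor) join their neighbor
    merged <- list(); merged_per <- logical()
    for (i in seq_len(nrow(pieces))) {
      short <- !is_per[i] && pieces[i, 2] - pieces[i, 1] < 15
      if (short && length(merged) > 0) {
        merged[[length(merged)]][2] <- pieces[i, 2]
      } else {
        merged[[length(merged) + 1L]] <- pieces[i, ]
        merged_per <- c(merged_per, is_per[i])
      }
    }
    if (length(merged) > 1 && !merged_per[1] &&
        merged[[1]][2] - merged[[1]][1] < 15) {
      merged[[2]][1] <- merged[[1]][1]
      merged <- merged[-1]
    }
    for (m in merged)
      out[[length(out) + 1L]] <- interval(shot$id, m[1], m[2])
  }
  out
}

# maximal runs of TRUE as half-open 0-based ranges
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- list()
  for (k in seq_along(r$values))
    if (r$values[k]) out[[length(out) + 1L]] <- c(starts[k], ends[k])
  out
}
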