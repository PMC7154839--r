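#' On-disk formats
#'
#' Readers and writers for every format the pipeline touches. Trajectories
#' are plain text (one per line: id, start frame, then x,y pairs), masks a
#' PNG sequence, flow a plain-text array dump, landmarks a CSV with columns
#' frame,name,x,y,visible, labels and intervals JSON (with a
#' `schema_version` field). All writers produce files their readers accept.
#'
#' @name io_formats
NULL

#' @param trajs list of trajectories (`list(id, start, points)`)
#' @param path file path
#' @rdname io_formats
#' @export
write_trajectories <- function(trajs, path) {
  lines <- vapply(trajs, function(tr) {
    paste(c(tr$id, tr$start,
            format(t(tr$points), digits = 17, trim = TRUE)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < 6 || length(v) %% 2 != 0)
      stop("malformed trajectory at line ", i,
           ": expected 'id start x1 y1 x2 y2 ...' with at least 2 points")
    if (any(!is.finite(v))) stop("non-finite coordinate at line ", i)
    list(id = as.integer(v[1]), start = as.integer(v[2]),
         points = matrix(v[-(1:2)], ncol = 2, byrow = TRUE))
  })
}

#' @param masks list of logical matrices
#' @param dir directory for the PNG sequence
#' @rdname io_formats
#' @export
write_masks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(masks))
    png::writePNG(masks[[t]] * 1,
                  file.path(dir, sprintf("mask_%05d.png", t - 1L)))
  invisible(dir)
}

#' @rdname io_formats
#' @export
read_masks <- function(dir) {
  files <- sort(list.files(dir, pattern = "^mask_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no mask PNGs found in ", dir)
  masks <- lapply(files, function(f) png::readPNG(f) > 0.5)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mask frames have inconsistent dimensions")
  masks
}

#' @param flow list of H x W x 2 arrays
#' @rdname io_formats
#' @export
write_flow <- function(flow, path) {
  d <- dim(flow[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(flow), d[1], d[2]), con)
  for (fl in flow) {
    if (!identical(dim(fl), c(d[1], d[2], 2L)) &&
        !identical(dim(fl), as.integer(c(d[1], d[2], 2))))
      stop("flow frames have inconsistent dimensions")
    writeLines(paste(format(as.vector(fl), digits = 17, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname io_formats
#' @export
read_flow <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hd <- as.integer(strsplit(readLines(con, 1), "\\s+")[[1]])
  if (length(hd) != 3) stop("malformed flow header")
  lapply(seq_len(hd[1]), function(t) {
    v <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
    if (length(v) != hd[2] * hd[3] * 2)
      stop("flow frame ", t - 1L, " has wrong size")
    array(v, dim = c(hd[2], hd[3], 2))
  })
}

#' @param landmarks data frame with columns frame, name, x, y, visible
#' @rdname io_formats
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("frame", "name", "x", "y", "visible")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "name", "x", "y", "visible")
  if (!all(need %in% names(lm))) stop("landmark CSV missing columns")
  lm$visible <- as.logical(lm$visible)
  lm[, need]
}

#' @param labels character vector, one behavior label per frame
#' @rdname io_formats
#' @export
write_labels <- function(labels, path) {
  jsonlite::write_json(list(schema_version = 1L, labels = labels), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_labels <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE)$labels)
}

#' Temporal intervals
#'
#' An interval is `list(shot_id, start, end, label)` with a half-open 0-based
#' frame range `[start, end)`.
#'
#' @param shot_id shot identifier
#' @param start,end half-open 0-based frame range
#' @param label optional ground-truth behavior label
#' @export
interval <- function(shot_id, start, end, label = NA_character_) {
  stopifnot(start >= 0, start < end)
  list(shot_id = shot_id, start = as.integer(start), end = as.integer(end),
       label = label)
}

#' @param intervals list of intervals
#' @param path file path
#' @rdname io_formats
#' @export
write_intervals <- function(intervals, path) {
  jsonlite::write_json(list(schema_version = 1L, intervals = intervals),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname io_formats
#' @export
read_intervals <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x$intervals, function(iv)
    interval(iv$shot_id, iv$start, iv$end,
             if (is.null(iv$label)) NA_character_ else iv$label))
}

#' Write / read a whole shot directory
#'
#' A shot directory bundles `trajectories.txt`, `masks/`, `flow.txt` and
#' optionally `landmarks.csv` and `labels.json`, all in the formats above.
#'
#' @param scene a `pot_scene` or `pot_shot`
#' @param dir directory to create
#' @rdname io_formats
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectories(scene$trajectories, file.path(dir, "trajectories.txt"))
  write_masks(scene$masks, file.path(dir, "masks"))
  write_flow(scene$flow, file.path(dir, "flow.txt"))
  if (!is.null(scene$landmarks))
    write_landmarks(scene$landmarks, file.path(dir, "landmarks.csv"))
  if (!is.null(scene$labels))
    write_labels(scene$labels, file.path(dir, "labels.json"))
  invisible(dir)
}

#' @param id shot identifier for the loaded shot
#' @rdname io_formats
#' @export
read_shot <- function(dir, id = basename(dir)) {
  masks <- read_masks(file.path(dir, "masks"))
  flow <- read_flow(file.path(dir, "flow.txt"))
  if (length(flow) != length(masks))
    stop("masks and flow disagree on the number of frames")
  if (!identical(dim(masks[[1]]), dim(flow[[1]])[1:2]))
    stop("masks and flow disagree on frame dimensions")
  lmp <- file.path(dir, "landmarks.csv")
  lbp <- file.path(dir, "labels.json")
  structure(list(
    id = id, frames = length(masks), width = ncol(masks[[1]]),
    height = nrow(masks[[1]]),
    trajectories = read_trajectories(file.path(dir, "trajectories.txt")),
    masks = masks, flow = flow,
    landmarks = if (file.exists(lmp)) read_landmarks(lmp) else NULL,
    labels = if (file.exists(lbp)) read_labels(lbp) else NULL
  ), class = "pot_shot")
}

#' Largest connected foreground component
#'
#' Keeps only the largest 8-connected component of a binary mask (the
#' preprocessing rule applied to foreground masks before feature extraction,
#' so that the biggest moving object drives the analysis). Ties are broken
#' in favor of the component containing the first foreground pixel in
#' row-major scan order.
#'
#' @param mask logical matrix
#' @return logical matrix of the same size, a subset of `mask`
#' @export
largest_component <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  idx <- which(mask)
  if (!length(idx)) {
    warning("all-zero mask: no foreground component")
    return(mask)
  }
  h <- nrow(mask); w <- ncol(mask)
  pos <- match(idx, idx)
  ii <- ((idx - 1) %% h) + 1; jj <- ((idx - 1) %/% h) + 1
  key <- function(i, j) (j - 1) * h + i
  edges <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    i2 <- ii + d[1]; j2 <- jj + d[2]
    ok <- i2 >= 1 & i2 <= h & j2 >= 1 & j2 <= w
    nb <- match(key(i2[ok], j2[ok]), idx)
    src <- which(ok)[!is.na(nb)]
    nb <- nb[!is.na(nb)]
    if (length(nb)) edges <- rbind(edges, cbind(pos[src], nb))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(idx),
                                                      seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # row-major order of the first pixel of each tied component
    rm_order <- (ii - 1) * w + (jj - 1)
    first_px <- vapply(best, function(cmp) min(rm_order[comp == cmp]),
                       numeric(1))
    best <- best[which.min(first_px)]
  }
  out <- matrix(FALSE, h, w)
  out[idx[comp == best]] <- TRUE
  out
}

#' Split frames into shots by histogram differences
#'
#' Places a shot boundary wherever the L1 difference between consecutive
#' per-frame color histograms exceeds `threshold`; the returned intervals
#' partition the frame range.
#'
#' @param frame_histograms matrix (frames x bins), one L1-normalized
#'   histogram per row
#' @param threshold boundary threshold on the L1 difference
#' @param shot_id identifier recorded in the returned intervals
#' @return list of intervals
#' @export
split_shots <- function(frame_histograms, threshold, shot_id = "video") {
  h <- as.matrix(frame_histograms)
  n <- nrow(h)
  if (n == 0) stop("no frames")
  if (n == 1) return(list(interval(shot_id, 0, 1)))
  d <- rowSums(abs(h[-1, , drop = FALSE] - h[-n, , drop = FALSE]))
  cuts <- which(d > threshold)  # boundary before frame cuts[i] (0-based cut)
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(i)
    interval(shot_id, starts[i], ends[i]))
}
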