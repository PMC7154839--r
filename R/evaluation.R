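#' Clustering quality: purity and adjusted Rand index
#'
#' Purity is the number of correctly clustered items divided by the total
#' (an item is correct when its label coincides with the most frequent label
#' of its cluster). The ARI additionally penalizes splitting items with the
#' same label across clusters and is adjusted so that random clusterings
#' score close to 0.
#'
#' @param assignments cluster assignments (NA entries are dropped from both
#'   vectors)
#' @param labels ground-truth labels of equal length
#' @return a scalar in `[0, 1]` (purity) or `[-1, 1]` (ARI)
#' @export
purity <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  keep <- !is.na(assignments)
  assignments <- assignments[keep]; labels <- labels[keep]
  if (!length(assignments)) stop("no items to evaluate")
  tab <- table(assignments, labels)
  sum(apply(tab, 1, max)) / length(assignments)
}

#' @rdname purity
#' @export
ari <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  keep <- !is.na(assignments)
  if (!sum(keep)) stop("no items to evaluate")
  mclust::adjustedRandIndex(assignments[keep], labels[keep])
}

#' Interval uniformity
#'
#' Fraction of an interval's frames carrying its most frequent behavior
#' label.
#'
#' @param iv an [interval()]
#' @param frame_labels per-frame labels of the interval's shot
#' @return scalar in `(0, 1]`
#' @export
uniformity <- function(iv, frame_labels) {
  lab <- frame_labels[(iv$start + 1):iv$end]
  max(table(lab)) / length(lab)
}

#' Majority label of an interval
#' @inheritParams uniformity
#' @return the most frequent frame label in the interval
#' @export
interval_majority_label <- function(iv, frame_labels) {
  lab <- frame_labels[(iv$start + 1):iv$end]
  names(which.max(table(lab)))
}

#' Count discovered behaviors across shots
#'
#' Counts, for each behavior label, the number of distinct shots that
#' contribute at least one interval whose majority label is that behavior
#' (so splitting one continuous behavior into many pieces does not inflate
#' the count).
#'
#' @param intervals list of intervals
#' @param labels_by_shot named list of per-frame label vectors, one per shot
#' @return named integer vector of per-behavior counts
#' @export
count_behaviors <- function(intervals, labels_by_shot) {
  pairs <- unique(t(vapply(intervals, function(iv)
    c(iv$shot_id,
      interval_majority_label(iv, labels_by_shot[[iv$shot_id]])),
    character(2))))
  table(pairs[, 2])
}

# per-frame object scale: max pairwise distance among visible landmarks
frame_scale <- function(lm) {
  p <- cbind(lm$x, lm$y)
  if (nrow(p) < 2) return(NA_real_)
  max(stats::dist(p))
}

#' Landmark alignment error of a mapping
#'
#' For each CMP frame and each landmark visible in both sequences, the
#' landmark of the first sequence is mapped onto the second (reverse
#' direction of the `u = f(v)` mapping) and compared with its annotated
#' location, and vice versa; each directional distance is normalized by the
#' object scale of its target frame (the maximum pairwise distance among
#' visible landmarks) and the two are averaged. The overall error is the
#' mean over all co-visible landmarks over all frames, and is invariant to
#' uniform scaling of both scenes.
#'
#' @param alignment a `pot_homography` or `pot_ttps`
#' @param landmarks_1,landmarks_2 landmark data frames (frame, name, x, y,
#'   visible) with frames 0-based and relative to the CMP window
#' @param frames number of CMP frames to evaluate
#' @return scalar error, or NA (with a warning) when no landmark is
#'   co-visible in any frame
#' @export
alignment_error <- function(alignment, landmarks_1, landmarks_2, frames) {
  errs <- c()
  for (t in 0:(frames - 1)) {
    l1 <- landmarks_1[landmarks_1$frame == t & landmarks_1$visible, ]
    l2 <- landmarks_2[landmarks_2$frame == t & landmarks_2$visible, ]
    common <- intersect(l1$name, l2$name)
    if (length(common) < 1) next
    s1 <- frame_scale(l1); s2 <- frame_scale(l2)
    if (is.na(s1) || is.na(s2) || s1 <= 0 || s2 <= 0) next
    p1 <- as.matrix(l1[match(common, l1$name), c("x", "y")])
    p2 <- as.matrix(l2[match(common, l2$name), c("x", "y")])
    fwd <- apply_mapping(alignment, p2, frame_t = t, direction = "forward")
    rev <- apply_mapping(alignment, p1, frame_t = t, direction = "reverse")
    errs <- c(errs, (l2(fwd - p1) / s1 + l2(rev - p2) / s2) / 2)
  }
  if (!length(errs)) {
    warning("no co-visible landmarks in any frame")
    return(NA_real_)
  }
  mean(errs)
}

#' Alignment correctness verdict
#'
#' An alignment is correct when the landmark error is below 0.18 and the
#' intersection-over-union of the sets of landmark names visible anywhere in
#' each sequence exceeds 0.5 (this prevents rewarding accidental alignments
#' of a few landmarks).
#'
#' @param error output of [alignment_error()]
#' @param landmarks_1,landmarks_2 landmark data frames for the two sequences
#' @param error_threshold,iou_threshold the correctness rule thresholds
#' @return list with `error`, `iou` and logical `correct`
#' @export
verdict <- function(error, landmarks_1, landmarks_2,
                    error_threshold = 0.18, iou_threshold = 0.5) {
  v1 <- unique(landmarks_1$name[landmarks_1$visible])
  v2 <- unique(landmarks_2$name[landmarks_2$visible])
  iou <- length(intersect(v1, v2)) / max(length(union(v1, v2)), 1)
  list(error = error, iou = iou,
       correct = !is.na(error) && error < error_threshold &&
         iou > iou_threshold)
}

#' Alignability oracle for a CMP
#'
#' Fits a homography in least squares to all co-visible ground-truth
#' landmark correspondences of the CMP and checks it with the correctness
#' rule: when even the landmark-fitted homography fails, the CMP is not
#' alignable.
#'
#' @param landmarks_1,landmarks_2 landmark data frames (CMP-relative)
#' @param frames number of CMP frames
#' @return list with `alignable`, `error`, `iou` and the fitted `H`
#' @export
alignable_oracle <- function(landmarks_1, landmarks_2, frames) {
  U <- NULL; V <- NULL
  for (t in 0:(frames - 1)) {
    l1 <- landmarks_1[landmarks_1$frame == t & landmarks_1$visible, ]
    l2 <- landmarks_2[landmarks_2$frame == t & landmarks_2$visible, ]
    common <- intersect(l1$name, l2$name)
    if (length(common) < 1) next
    U <- rbind(U, as.matrix(l1[match(common, l1$name), c("x", "y")]))
    V <- rbind(V, as.matrix(l2[match(common, l2$name), c("x", "y")]))
  }
  if (is.null(U) || nrow(U) < 4)
    return(list(alignable = FALSE, error = NA_real_, iou = 0, H = NULL))
  H <- dlt_fit(V, U)
  al <- structure(list(H = H), class = "pot_homography")
  err <- alignment_error(al, landmarks_1, landmarks_2, frames)
  v <- verdict(err, landmarks_1, landmarks_2)
  list(alignable = v$correct, error = err, iou = v$iou, H = H)
}

#' Precision-recall over an outlier-fraction sweep
#'
#' For each operating point (one column of the input matrices, typically one
#' maximum outlier fraction allowed during homography fitting): n = number
#' of CMPs returned, c = number correctly aligned, a = number of alignable
#' CMPs. Precision is c/n (1 by convention when nothing is returned) and
#' recall is c/a. Average precision is the trapezoidal area over recall.
#'
#' @param returned CMPs x sweep logical matrix: alignment returned
#' @param correct CMPs x sweep logical matrix: returned and correct
#' @param alignable length-CMPs logical vector
#' @return list with `curve` (data frame sweep point, n, c, precision,
#'   recall) and `average_precision`
#' @export
precision_recall <- function(returned, correct, alignable) {
  returned <- as.matrix(returned); correct <- as.matrix(correct)
  stopifnot(dim(returned) == dim(correct),
            nrow(returned) == length(alignable))
  a <- sum(alignable)
  if (a == 0) warning("no alignable CMPs: recall undefined")
  n <- colSums(returned)
  cc <- colSums(correct & returned)
  precision <- ifelse(n > 0, cc / n, 1)
  recall <- if (a > 0) cc / a else rep(NA_real_, length(n))
  curve <- data.frame(point = seq_along(n), n = n, c = cc,
                      precision = precision, recall = recall)
  ap <- NA_real_
  if (a > 0) {
    o <- order(recall)
    r <- c(0, recall[o]); p <- c(precision[o][1], precision[o])
    ap <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  }
  list(curve = curve, average_precision = ap)
}
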