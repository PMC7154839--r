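#' Build a k-means codebook of descriptors
#'
#' Runs k-means (Euclidean) several times and keeps the run with the lowest
#' within-cluster sum of squares; the sample is capped at one million
#' descriptors. When the number of distinct descriptors equals `V` they are
#' used as the centroids directly (energy 0).
#'
#' @param descriptors N x d matrix
#' @param V codebook size (>= 2; at most N)
#' @param restarts number of k-means restarts
#' @param seed integer seed (restart r uses `seed + r`)
#' @param max_sample cap on the number of descriptors used
#' @return a `pot_codebook` with a `centroids` matrix and `energy`
#' @export
build_codebook <- function(descriptors, V = 800, restarts = 8, seed = 1,
                           max_sample = 1e6) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < V)
    stop("need at least V descriptors to build a codebook of size V")
  stopifnot(V >= 2)
  if (nrow(descriptors) > max_sample) {
    set.seed(seed)
    descriptors <- descriptors[sample(nrow(descriptors), max_sample), ,
                               drop = FALSE]
  }
  uniq <- unique(descriptors)
  if (nrow(uniq) < V)
    stop("fewer distinct descriptors (", nrow(uniq), ") than codewords")
  if (nrow(uniq) == V) {
    km <- list(centers = uniq, tot.withinss = 0)
  } else {
    km <- NULL
    for (r in seq_len(restarts)) {
      set.seed(seed + r)
      cand <- suppressWarnings(
        stats::kmeans(descriptors, centers = V, iter.max = 100))
      if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
    }
  }
  structure(list(centroids = unname(km$centers), energy = km$tot.withinss,
                 seed = seed), class = "pot_codebook")
}

# Hard nearest-centroid assignment (Euclidean), vectorized.
assign_codewords <- function(descriptors, codebook) {
  X <- as.matrix(descriptors)
  C <- codebook$centroids
  if (ncol(X) != ncol(C)) stop("descriptor dimension does not match codebook")
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  max.col(-d2, ties.method = "first")
}

#' Bag-of-words histogram
#'
#' Hard nearest-centroid assignment followed by L1 normalization. An empty
#' descriptor set yields the zero histogram, flagged with attribute
#' `empty = TRUE`.
#'
#' @param descriptors N x d matrix (N may be 0)
#' @param codebook a [build_codebook()] result
#' @return numeric vector of length V summing to 1 (or 0 when empty)
#' @export
bow <- function(descriptors, codebook) {
  V <- nrow(codebook$centroids)
  if (is.null(descriptors) || nrow(as.matrix(descriptors)) == 0) {
    h <- rep(0, V)
    attr(h, "empty") <- TRUE
    return(h)
  }
  w <- assign_codewords(descriptors, codebook)
  h <- tabulate(w, nbins = V)
  h / sum(h)
}

#' Exponential histogram-intersection distances between intervals
#'
#' `interval_distance()` is `-exp(-(1 - HI(b_u, b_v)))` with HI the
#' histogram intersection of two L1-normalized BoW histograms; it lies in
#' `[-1, -exp(-1)]`, equals -1 for identical histograms and `-exp(-1)` for
#' disjoint ones, and is more negative the more similar the intervals.
#' `multichannel_distance()` combines C feature channels as
#' `-exp(-sum_i (1 - HI_i) / A_i)` where `A_i` is the dataset-average of
#' `(1 - HI)` for channel i (see [channel_scales()]); with one channel and
#' `A = 1` it reduces to `interval_distance()`.
#'
#' @param b_u,b_v L1-normalized histograms of equal length
#' @return a scalar distance in `[-1, -exp(-1)]`
#' @export
interval_distance <- function(b_u, b_v) {
  if (length(b_u) != length(b_v)) stop("histograms have different sizes")
  -exp(-(1 - sum(pmin(b_u, b_v))))
}

#' @param channels_u,channels_v lists of per-channel histograms
#' @param A per-channel average dissimilarities
#' @rdname interval_distance
#' @export
multichannel_distance <- function(channels_u, channels_v, A) {
  stopifnot(length(channels_u) == length(channels_v),
            length(A) == length(channels_u))
  s <- 0
  for (i in seq_along(A)) {
    if (length(channels_u[[i]]) != length(channels_v[[i]]))
      stop("histograms have different sizes in channel ", i)
    hi <- sum(pmin(channels_u[[i]], channels_v[[i]]))
    s <- s + (1 - hi) / A[i]
  }
  -exp(-s)
}

#' Per-channel average dissimilarity
#'
#' Computes `A_i`, the average of `1 - HI` over all pairs of items for each
#' channel, on the collection being clustered.
#'
#' @param channel_bows list (per channel) of N x V histogram matrices
#' @return numeric vector of channel scales (floored at 1e-8)
#' @export
channel_scales <- function(channel_bows) {
  vapply(channel_bows, function(B) {
    B <- as.matrix(B)
    n <- nrow(B)
    if (n < 2) return(1)
    tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) {
      hi <- colSums(pmin(t(B[(i + 1):n, , drop = FALSE]), B[i, ]))
      tot <- tot + sum(1 - hi); cnt <- cnt + (n - i)
    }
    max(tot / cnt, 1e-8)
  }, numeric(1))
}

#' Cluster intervals by complete linkage
#'
#' Agglomerative complete-linkage clustering on the pairwise exponential
#' histogram-intersection distance matrix, cut at `k` clusters. Intervals
#' with an empty BoW carry no motion evidence; they are excluded from the
#' clustering and reported as NA with a warning.
#'
#' @param bows N x V matrix of interval histograms (rows), or a list of
#'   per-channel matrices for multichannel distances
#' @param k number of clusters
#' @param A optional channel scales for the multichannel case (computed on
#'   the input by default)
#' @return integer vector of cluster assignments (NA for empty intervals),
#'   with the `hclust` tree in attribute `tree`
#' @export
cluster_intervals <- function(bows, k, A = NULL) {
  channels <- if (is.list(bows) && !is.data.frame(bows)) bows else list(bows)
  channels <- lapply(channels, as.matrix)
  n <- nrow(channels[[1]])
  stopifnot(k >= 1, k <= n)
  nonempty <- rowSums(channels[[1]]) > 0
  if (any(!nonempty))
    warning(sum(!nonempty), " interval(s) with empty BoW excluded")
  use <- which(nonempty)
  channels_use <- lapply(channels, function(B) B[use, , drop = FALSE])
  if (is.null(A)) A <- channel_scales(channels_use)
  m <- length(use)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- multichannel_distance(
      lapply(channels_use, function(B) B[i, ]),
      lapply(channels_use, function(B) B[j, ]), A)
  }
  k_eff <- min(k, m)
  tree <- stats::hclust(stats::as.dist(D), method = "complete")
  cl <- stats::cutree(tree, k = k_eff)
  out <- rep(NA_integer_, n)
  out[use] <- cl
  attr(out, "tree") <- tree
  out
}
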