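#' Dynamic-time-warping distance between two series
#'
#' Banded (Sakoe-Chiba) DTW with symmetric steps and squared local cost;
#' returns the square root of the accumulated cost.
#'
#' @param x,y numeric series.
#' @param band band half-width in samples (default 10).
#' @return distance (>= 0).
#' @export
dtw_distance <- function(x, y, band = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("DTW inputs must be complete")
  band <- max(band, abs(length(x) - length(y)))
  dtw_band_cpp(x, y, as.integer(band))
}

#' Hierarchical clustering of autocorrelation functions with time warping
#'
#' Pairwise DTW distances between per-pair ACFs, agglomerative clustering,
#' and a cut at `k` clusters; centroids are per-cluster mean ACFs. Cluster
#' labels are renumbered by increasing centroid ACF depth so that label 1 is
#' the strongest oscillator class.
#'
#' @param acfs matrix with one ACF per row (equal lag grids).
#' @param k number of clusters (default 5).
#' @param band Sakoe-Chiba band half-width in lags (default 10).
#' @param method hclust linkage (default "average").
#' @param refine number of medoid-reassignment passes applied after the tree
#'   cut (default 0 = plain hierarchical labels); each pass reassigns every
#'   series to its nearest cluster medoid, stabilising boundary assignments.
#' @return object of class `cluster_assignment`: `labels`, `centroids`
#'   (k x lags), `depths`, `tree` (hclust), `dist`.
#' @export
dtw_cluster <- function(acfs, k = 5, band = 10, method = "average",
                        refine = 0) {
  acfs <- as.matrix(acfs)
  n <- nrow(acfs)
  if (n < k) stop("fewer series than clusters")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dtw_distance(acfs[i, ], acfs[j, ], band = band)
    }
  }
  tree <- stats::hclust(stats::as.dist(D), method = method)
  raw <- stats::cutree(tree, k = k)
  for (r in seq_len(refine)) {
    med <- vapply(seq_len(k), function(g) {
      w <- which(raw == g)
      w[which.min(colSums(D[w, w, drop = FALSE]))]
    }, 0L)
    new <- apply(D[, med, drop = FALSE], 1, which.min)
    if (all(new == raw)) break
    raw <- new
  }
  if (length(unique(raw)) < k) stop("refinement collapsed a cluster; reduce refine")
  cent <- t(vapply(seq_len(k), function(g) colMeans(acfs[raw == g, , drop = FALSE]),
                   numeric(ncol(acfs))))
  depth <- apply(cent, 1, min)
  relabel <- order(depth)  # deepest (strongest oscillator) first
  map <- match(seq_len(k), relabel)
  structure(list(labels = map[raw], centroids = cent[relabel, , drop = FALSE],
                 depths = depth[relabel], tree = tree,
                 dist = stats::as.dist(D)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d series in %d clusters; centroid depths %s>\n",
              length(x$labels), nrow(x$centroids),
              paste(round(x$depths, 2), collapse = ", ")))
  invisible(x)
}

#' Best label agreement between two clusterings
#'
#' Maximises agreement over label permutations (greedy Hungarian-style
#' assignment on the confusion matrix; exact for small k via full
#' enumeration when k <= 6).
#'
#' @param truth,labels integer label vectors of equal length.
#' @return agreement fraction in \[0, 1\].
#' @export
matched_accuracy <- function(truth, labels) {
  t_lev <- sort(unique(truth)); l_lev <- sort(unique(labels))
  C <- table(factor(truth, t_lev), factor(labels, l_lev))
  k <- max(length(t_lev), length(l_lev))
  M <- matrix(0, k, k)
  M[seq_along(t_lev), seq_along(l_lev)] <- C
  if (k <= 6) {
    perms <- permute_all(seq_len(k))
    best <- max(vapply(perms, function(p) sum(M[cbind(seq_len(k), p)]), 0))
  } else {
    best <- 0; used <- integer(0)
    for (i in order(-apply(M, 1, max))) {
      j <- order(-M[i, ])
      j <- j[!j %in% used][1]
      best <- best + M[i, j]; used <- c(used, j)
    }
  }
  best / length(truth)
}

permute_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permute_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
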