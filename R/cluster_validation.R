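# Internal validity metrics for clonal clusterings of VAF matrices:
# Davies-Bouldin, Dunn, mean silhouette and connectivity, plus a table
# comparing alternative labelings of the same cells. Distances are
# Euclidean, optionally on a per-variant standardized matrix.

check_clustering <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    stop("labels length does not match the number of points")
  split(seq_len(nrow(X)), labels)
}

#' Per-variant standardization of a VAF matrix
#'
#' Centers and scales each column; zero-variance columns are left centered
#' (all zeros) rather than producing NaNs.
#'
#' @param X Point x feature matrix.
#' @return The scaled matrix.
#' @export
scale_vaf <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd, `/`)
}

#' Davies-Bouldin index
#'
#' `DB = (1/K) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean Euclidean distance of cluster i's points to their centroid and
#' `M_ij` the distance between centroids. Lower values indicate tighter,
#' better-separated clusters.
#'
#' @param X Point x feature matrix (e.g. a scaled VAF matrix).
#' @param labels Cluster labels, one per row of `X`.
#' @return The DB index.
#' @export
davies_bouldin <- function(X, labels) {
  groups <- check_clustering(X, labels)
  if (length(groups) < 2L) stop("need at least 2 clusters")
  X <- as.matrix(X)
  cents <- t(vapply(groups, function(idx)
    colMeans(X[idx, , drop = FALSE]), numeric(ncol(X))))
  S <- vapply(seq_along(groups), function(i) {
    d <- sweep(X[groups[[i]], , drop = FALSE], 2L, cents[i, ])
    mean(sqrt(rowSums(d^2)))
  }, 0)
  K <- length(groups)
  ratios <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    M <- sqrt(sum((cents[i, ] - cents[j, ])^2))
    if (M == 0)
      stop("coincident centroids for clusters '", names(groups)[i],
           "' and '", names(groups)[j], "'")
    ratios[i, j] <- (S[i] + S[j]) / M
  }
  mean(apply(ratios, 1L, max, na.rm = TRUE))
}

#' Dunn index
#'
#' Minimum between-cluster point-to-point distance divided by the maximum
#' within-cluster diameter; larger is better. A clustering of singletons
#' only (all diameters zero) returns `Inf` with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams davies_bouldin
#' @return The Dunn index.
#' @export
dunn_index <- function(X, labels) {
  groups <- check_clustering(X, labels)
  if (length(groups) < 2L) stop("need at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  lab <- as.character(labels)
  same <- outer(lab, lab, `==`)
  diag(same) <- NA
  inter <- min(D[!same & !is.na(same)])
  diam <- max(D[same & !is.na(same)], 0)
  if (diam == 0) return(structure(Inf, degenerate = TRUE))
  inter / diam
}

#' Mean silhouette width
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' to the own cluster's other points and `b(i)` the smallest mean distance
#' to another cluster; singleton clusters contribute `s = 0`.
#'
#' @inheritParams davies_bouldin
#' @return Mean silhouette over all points, in `[-1, 1]`.
#' @export
mean_silhouette <- function(X, labels) {
  groups <- check_clustering(X, labels)
  if (length(groups) < 2L) stop("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(X))
  lab <- as.character(labels)
  s <- vapply(seq_along(lab), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(names(groups), lab[i]), function(g)
      mean(D[i, groups[[g]]]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Connectivity score
#'
#' For every point, its `L` nearest neighbours are inspected in order;
#' the j-th neighbour adds `1/j` when it is not co-clustered with the
#' point. Lower is better (0 when clusters respect local neighbourhoods).
#' Distance ties are broken by point index for determinism.
#'
#' @inheritParams davies_bouldin
#' @param L Neighbour depth (default 10, the conventional choice for this
#'   validation scheme).
#' @return The connectivity score (>= 0).
#' @export
connectivity <- function(X, labels, L = 10L) {
  if (L < 1L) stop("L must be >= 1")
  groups <- check_clustering(X, labels)
  n <- nrow(as.matrix(X))
  if (L >= n) stop("L must be below the number of points")
  D <- as.matrix(stats::dist(X))
  lab <- as.character(labels)
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(L)]
    mism <- lab[ord] != lab[i]
    total <- total + sum((1 / seq_len(L))[mism])
  }
  total
}

#' Compare alternative clusterings of the same VAF matrix
#'
#' Computes all four validity metrics for each labeling and ranks by
#' ascending Davies-Bouldin (the headline comparison statistic).
#'
#' @param X Point x feature matrix shared by all labelings.
#' @param labelings Named list of label vectors.
#' @param L Neighbour depth for [connectivity()].
#' @param scale Standardize `X` per feature first (default `TRUE`).
#' @return A data.frame with one row per labeling: `labeling`,
#'   `davies_bouldin`, `dunn`, `mean_silhouette`, `connectivity`,
#'   `n_clusters`, `n_points`, `rank` (by DB ascending).
#' @export
compare_clusterings <- function(X, labelings, L = 10L, scale = TRUE) {
  if (length(labelings) < 2L) stop("need at least 2 labelings to compare")
  if (is.null(names(labelings)))
    names(labelings) <- paste0("labeling", seq_along(labelings))
  Xs <- if (scale) scale_vaf(X) else as.matrix(X)
  rows <- lapply(names(labelings), function(nm) {
    lab <- labelings[[nm]]
    data.frame(labeling = nm,
               davies_bouldin = davies_bouldin(Xs, lab),
               dunn = as.numeric(dunn_index(Xs, lab)),
               mean_silhouette = mean_silhouette(Xs, lab),
               connectivity = connectivity(Xs, lab, L),
               n_clusters = length(unique(lab)),
               n_points = nrow(Xs), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$rank <- rank(res$davies_bouldin, ties.method = "min")
  res[order(res$rank), , drop = FALSE]
}
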