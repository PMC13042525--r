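# Spatial architecture of clones in spot-based transcriptomics: boundary
# and radial distances, Moran's I with a permutation null, and
# peripheral/central classification.

spot_xy <- function(spots) {
  cbind(x = spots$pxl_col_in_fullres, y = spots$pxl_row_in_fullres)
}

in_tissue_spots <- function(spots) {
  spots[!is.na(spots$in_tissue) & spots$in_tissue == 1L, , drop = FALSE]
}

#' Distance of every spot to the tissue convex hull
#'
#' The hull is computed over all in-tissue spots of the replicate (the 2D
#' tissue section), and each spot's distance is the minimum Euclidean
#' distance to any hull edge segment -- zero for hull vertices, small for
#' peripheral spots.
#'
#' @param spots A `SpotGeometry` data.frame for one replicate.
#' @return A list: `per_spot` (numeric, named by spot barcode) and
#'   `per_clone` (mean over each clone's spots; spots without a clone
#'   label are skipped).
#' @export
hull_boundary_distances <- function(spots) {
  spots <- in_tissue_spots(spots)
  xy <- spot_xy(spots)
  if (nrow(xy) < 3L || is_collinear(xy))
    stop("degenerate (collinear) tissue hull in replicate '",
         spots$replicate_id[1L], "'")
  hull <- grDevices::chull(xy)
  d <- min_dist_to_polygon(xy, xy[hull, , drop = FALSE])
  names(d) <- spots$barcode
  list(per_spot = d, per_clone = clone_means(d, spots$clone))
}

is_collinear <- function(xy) {
  if (nrow(xy) < 3L) return(TRUE)
  s <- svd(scale(xy, center = TRUE, scale = FALSE))$d
  s[2L] < 1e-9 * max(s[1L], 1)
}

# Min distance from each point to the closed polygon given by vertices (in
# order). Vectorized over edges.
min_dist_to_polygon <- function(pts, poly) {
  n_edge <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (e in seq_len(n_edge)) {
    a <- poly[e, ]
    b <- poly[if (e == n_edge) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      de <- sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2)
    } else {
      t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(pmax(t, 0), 1)
      px <- a[1L] + t * ab[1L]
      py <- a[2L] + t * ab[2L]
      de <- sqrt((pts[, 1L] - px)^2 + (pts[, 2L] - py)^2)
    }
    d <- pmin(d, de)
  }
  d
}

clone_means <- function(values, clone) {
  ok <- !is.na(clone)
  if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
  tapply(values[ok], clone[ok], mean)
}

#' Distance of every spot to the tissue centroid
#'
#' The centroid is the arithmetic mean of all in-tissue spot coordinates;
#' larger per-clone means indicate a more peripheral clone.
#'
#' @inheritParams hull_boundary_distances
#' @return A list: `per_spot`, `per_clone`, `centroid`.
#' @export
radial_distances <- function(spots) {
  spots <- in_tissue_spots(spots)
  if (nrow(spots) < 1L) stop("no in-tissue spots")
  xy <- spot_xy(spots)
  ctr <- colMeans(xy)
  d <- sqrt((xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2)
  names(d) <- spots$barcode
  list(per_spot = d, per_clone = clone_means(d, spots$clone), centroid = ctr)
}

#' Symmetrized k-nearest-neighbour weight matrix
#'
#' Binary weights: `w_ij = 1` if j is among i's k nearest neighbours or
#' vice versa, `w_ii = 0`. The default `k = 6` mirrors the hexagonal
#' packing of Visium spots.
#'
#' @param xy Two-column coordinate matrix.
#' @param k Number of neighbours.
#' @return A sparse symmetric 0/1 matrix.
#' @export
knn_weights <- function(xy, k = 6L) {
  n <- nrow(xy)
  if (k >= n) stop("k must be below the number of spots")
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  idx <- apply(D, 1L, function(row) order(row)[seq_len(k)])
  i <- rep(seq_len(n), each = k)
  j <- as.vector(idx)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  W <- ((W + Matrix::t(W)) > 0) * 1
  methods::as(W, "generalMatrix")
}

#' Moran's I of a clone indicator with a permutation null
#'
#' With `x_i = 1` when spot i belongs to the clone and `z_i = x_i - mean(x)`,
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` where `W` is the total
#' weight. Positive values indicate that spots of the clone aggregate in
#' space. Significance is assessed by permuting the labels over spots:
#' `p = (1 + #[I* >= I_obs]) / (1 + n_perm)`.
#'
#' @param spots A `SpotGeometry` data.frame for one replicate (or `NULL`
#'   when `x` and `W` are given directly).
#' @param clone Clone label whose indicator is tested.
#' @param k_neighbors Neighbourhood size for [knn_weights()].
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutations.
#' @param x Optional explicit 0/1 indicator (overrides `spots`/`clone`).
#' @param W Optional explicit weight matrix (overrides the kNN graph).
#' @return A list: `I`, `perm_p`, `n`, or `I = NA` with a `reason` when
#'   the indicator has no variance.
#' @export
morans_i <- function(spots = NULL, clone = NULL, k_neighbors = 6L,
                     n_perm = 999L, seed = 1L, x = NULL, W = NULL) {
  if (is.null(x)) {
    spots <- in_tissue_spots(spots)
    x <- as.integer(!is.na(spots$clone) & spots$clone == clone)
  }
  n <- length(x)
  if (sum(x) < 2L || sum(1 - x) < 2L)
    return(list(I = NA_real_, perm_p = NA_real_, n = n,
                reason = "indicator has (near-)zero variance"))
  if (is.null(W)) W <- knn_weights(spot_xy(spots), k_neighbors)
  Wtot <- sum(W)
  z <- x - mean(x)
  denom <- sum(z^2)
  I_obs <- (n / Wtot) * as.numeric(z %*% (W %*% z)) / denom
  perm_p <- NA_real_
  if (n_perm > 0L) {
    P <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(z), numeric(n))
    })
    # z'z and W are permutation-invariant; batch the quadratic forms
    I_star <- (n / Wtot) * colSums(as.matrix(W %*% P) * P) / denom
    perm_p <- (1 + sum(I_star >= I_obs)) / (1 + n_perm)
  }
  list(I = I_obs, perm_p = perm_p, n = n)
}

#' Spatial metrics for every clone of every replicate
#'
#' Convenience wrapper computing mean boundary distance, mean radial
#' distance and Moran's I (with permutation p) per (replicate, clone).
#'
#' @param spot_list List of per-replicate `SpotGeometry` data.frames.
#' @param k_neighbors,n_perm,seed Passed to [morans_i()].
#' @return A data.frame with one row per (replicate, clone):
#'   `replicate_id`, `clone`, `n_spots`, `mean_boundary_distance`,
#'   `mean_radial_distance`, `morans_I`, `perm_p`, `position_class`.
#' @export
spatial_metrics <- function(spot_list, k_neighbors = 6L, n_perm = 999L,
                            seed = 1L) {
  if (inherits(spot_list, "data.frame")) spot_list <- list(spot_list)
  out <- list()
  for (r in seq_along(spot_list)) {
    spots <- in_tissue_spots(spot_list[[r]])
    rid <- spots$replicate_id[1L]
    bd <- hull_boundary_distances(spots)$per_clone
    rd <- radial_distances(spots)$per_clone
    W <- knn_weights(spot_xy(spots), k_neighbors)
    clones <- sort(names(bd))
    rows <- lapply(clones, function(cl) {
      mi <- morans_i(x = as.integer(spots$clone == cl), W = W,
                     n_perm = n_perm, seed = derive_seed(seed, r * 1000L))
      data.frame(replicate_id = rid, clone = cl,
                 n_spots = sum(spots$clone == cl, na.rm = TRUE),
                 mean_boundary_distance = unname(bd[cl]),
                 mean_radial_distance = unname(rd[cl]),
                 morans_I = mi$I, perm_p = mi$perm_p,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$position_class <- classify_positions(rows$mean_boundary_distance,
                                              rows$clone)
    out[[r]] <- rows
  }
  do.call(rbind, out)
}

#' Classify clones of one replicate as peripheral / central / intermediate
#'
#' The clone with the smallest mean boundary distance is `"peripheral"`,
#' the one with the largest is `"central"`, all others `"intermediate"`.
#' Exact ties are broken by clone id (ascending) with a warning.
#'
#' @param boundary_means Numeric vector of per-clone mean boundary
#'   distances.
#' @param clone_ids Matching clone identifiers.
#' @return Character vector of position classes, parallel to the input.
#' @export
classify_positions <- function(boundary_means, clone_ids) {
  stopifnot(length(boundary_means) == length(clone_ids))
  if (length(boundary_means) < 2L)
    return(rep("intermediate", length(boundary_means)))
  if (anyDuplicated(boundary_means))
    warning("tied boundary distances; ties broken by clone id")
  ord <- order(boundary_means, clone_ids)
  cls <- rep("intermediate", length(boundary_means))
  cls[ord[1L]] <- "peripheral"
  cls[ord[length(ord)]] <- "central"
  cls
}

#' Paired t-tests of a distance metric between clones across replicates
#'
#' For each clone pair, a two-sided paired t-test on the per-replicate
#' values (df = number of replicates - 1). Pairs with zero-variance
#' differences report a missing p with the reason.
#'
#' @param metrics A data.frame with columns `replicate_id`, `clone`, and
#'   the metric named by `value_col`.
#' @param value_col Which metric column to compare.
#' @return A data.frame `clone_a`, `clone_b`, `t`, `df`, `p`, `note`.
#' @export
compare_clones_across_replicates <- function(metrics,
                                             value_col = "mean_boundary_distance") {
  wide <- stats::reshape(
    metrics[, c("replicate_id", "clone", value_col)],
    idvar = "replicate_id", timevar = "clone", direction = "wide")
  clones <- sub(paste0("^", value_col, "\\."), "",
                names(wide)[-1L])
  if (nrow(wide) < 2L) stop("need at least 2 replicates for paired tests")
  rows <- list()
  for (a in seq_along(clones)[-length(clones)]) {
    for (b in seq((a + 1L), length(clones))) {
      va <- wide[[a + 1L]]; vb <- wide[[b + 1L]]
      diffs <- va - vb
      if (stats::sd(diffs) == 0 || anyNA(diffs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          clone_a = clones[a], clone_b = clones[b], t = NA_real_,
          df = length(diffs) - 1L, p = NA_real_,
          note = "zero-variance or missing differences",
          stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(va, vb, paired = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          clone_a = clones[a], clone_b = clones[b],
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Attach clone labels to spot positions by barcode
#'
#' Inner join on the spot barcode: unmatched spots keep a missing clone
#' (and are therefore excluded from metrics); zero matches is an error.
#'
#' @param spots A `SpotGeometry` data.frame (e.g. from
#'   [read_visium_positions()]).
#' @param labels Named character vector (or data.frame `cell`/`barcode`
#'   and `clone`) of clone labels keyed by barcode.
#' @return The `spots` data.frame with its `clone` column filled; the
#'   number of matched spots is attached as attribute `n_matched`.
#' @export
attach_clone_labels <- function(spots, labels) {
  if (is.data.frame(labels)) {
    key <- if ("barcode" %in% names(labels)) "barcode" else "cell"
    labels <- stats::setNames(as.character(labels$clone), labels[[key]])
  }
  matched <- intersect(spots$barcode, names(labels))
  if (length(matched) == 0L)
    stop("no spot barcode matches a clone label")
  spots$clone <- unname(labels[spots$barcode])
  attr(spots, "n_matched") <- length(matched)
  spots
}
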