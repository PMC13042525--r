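make_spots <- function(x, y, clone = NA_character_, in_tissue = 1L,
                       rid = "rep1") {
  sg <- data.frame(replicate_id = rid,
                   barcode = sprintf("s%03d", seq_along(x)),
                   in_tissue = in_tissue,
                   array_row = seq_along(x), array_col = seq_along(x),
                   pxl_row_in_fullres = y, pxl_col_in_fullres = x,
                   clone = clone, stringsAsFactors = FALSE)
  class(sg) <- c("SpotGeometry", "data.frame")
  sg
}

test_that("boundary distances on a unit square match hand geometry", {
  # 4 corners + centre + an off-centre point of a unit square
  spots <- make_spots(c(0, 1, 1, 0, 0.5, 0.25),
                      c(0, 0, 1, 1, 0.5, 0.5),
                      clone = c("a", "a", "b", "b", "b", "a"))
  d <- hull_boundary_distances(spots)$per_spot
  expect_equal(unname(d[1:4]), rep(0, 4))        # hull vertices
  expect_equal(unname(d[5]), 0.5)                # centre
  expect_equal(unname(d[6]), 0.25)               # nearest edge x = 0
  per <- hull_boundary_distances(spots)$per_clone
  expect_equal(unname(per["a"]), mean(c(0, 0, 0.25)))
  expect_equal(unname(per["b"]), mean(c(0, 0, 0.5)))
})

test_that("collinear or tiny tissues are rejected as degenerate", {
  line <- make_spots(1:5, 2 * (1:5) + 3)
  expect_error(hull_boundary_distances(line), "degenerate")
  expect_error(hull_boundary_distances(make_spots(c(0, 1), c(0, 0))),
               "degenerate")
})

test_that("point-to-polygon distance matches a brute-force oracle", {
  set.seed(9)
  poly <- cbind(c(0, 4, 5, 2, -1), c(0, -1, 3, 5, 2))
  pts <- cbind(runif(50, -2, 6), runif(50, -2, 6))
  d <- min_dist_to_polygon(pts, poly)
  # oracle: dense sampling of every edge
  oracle <- sapply(seq_len(nrow(pts)), function(i) {
    best <- Inf
    for (e in seq_len(nrow(poly))) {
      a <- poly[e, ]; b <- poly[if (e == nrow(poly)) 1 else e + 1, ]
      t <- seq(0, 1, length.out = 2001)
      ex <- a[1] + t * (b[1] - a[1]); ey <- a[2] + t * (b[2] - a[2])
      best <- min(best, sqrt((pts[i, 1] - ex)^2 + (pts[i, 2] - ey)^2))
    }
    best
  })
  expect_equal(d, oracle, tolerance = 1e-5)
})

test_that("radial distances use the centroid of in-tissue spots only", {
  spots <- make_spots(c(0, 2, 1, 100), c(0, 0, 1, 100),
                      in_tissue = c(1L, 1L, 1L, 0L))
  r <- radial_distances(spots)
  expect_equal(unname(r$centroid), c(1, 1 / 3))
  expect_equal(length(r$per_spot), 3L)
  expect_equal(unname(r$per_spot[3]), 2 / 3)
})

test_that("the kNN weight matrix is symmetric, hollow and binary", {
  set.seed(4)
  xy <- cbind(runif(40), runif(40))
  W <- knn_weights(xy, k = 6L)
  expect_true(Matrix::isSymmetric(W))
  expect_true(all(Matrix::diag(W) == 0))
  expect_true(all(W@x %in% c(0, 1)))
  expect_true(all(Matrix::rowSums(W) >= 6))   # union can only add neighbours
  expect_error(knn_weights(xy[1:3, ], k = 6L), "below the number of spots")
})

test_that("Moran's I reproduces closed-form values on a rook grid", {
  # perfect 4x4 checkerboard: every neighbour pair disagrees, I = -1
  W <- rook_grid_weights(4, 4)
  chk <- as.integer(outer(1:4, 1:4, function(r, c) (r + c) %% 2))
  res <- morans_i(x = chk, W = W, n_perm = 0L)
  expect_equal(res$I, -1)
  # two solid half-planes: hand-computed I on the 4x4 grid
  half <- as.integer(outer(1:4, 1:4, function(r, c) r <= 2))
  z <- half - mean(half)
  oracle <- (16 / sum(W)) * as.numeric(z %*% (W %*% z)) / sum(z^2)
  res2 <- morans_i(x = half, W = W, n_perm = 499L, seed = 1L)
  expect_equal(res2$I, oracle)
  expect_lt(res2$perm_p, 0.05)
  # constant indicator has no variance
  expect_true(is.na(morans_i(x = rep(1L, 16), W = W)$I))
})

test_that("the permutation null is calibrated at the nominal level", {
  set.seed(12)
  xy <- cbind(runif(60), runif(60))
  W <- knn_weights(xy, k = 6L)
  pvals <- vapply(1:400, function(i) {
    x <- as.integer(sample(rep(c(0L, 1L), each = 30)))
    morans_i(x = x, W = W, n_perm = 199L, seed = i)$perm_p
  }, 0)
  rate <- mean(pvals <= 0.05)
  # binomial band around 0.05 at n = 400
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 1 / 200)
})

test_that("position classes follow the boundary-distance ranking", {
  expect_equal(classify_positions(c(5, 1, 9), c("a", "b", "c")),
               c("intermediate", "peripheral", "central"))
  expect_warning(cls <- classify_positions(c(1, 1), c("b", "a")), "tied")
  expect_equal(cls, c("central", "peripheral"))
})

test_that("simulated zonation is detected across replicates", {
  cfg <- generator_config(n_cells = 50, n_informative = 2,
                          n_noise_variants = 0, mean_dp = 2,
                          n_spatial_replicates = 3,
                          spots_per_replicate = 150, seed = 60L)
  sim <- simulate_clonal_population(cfg)
  spots <- simulate_spatial(sim$truth, cfg)
  met <- spatial_metrics(spots, n_perm = 199L, seed = 3L)
  expect_equal(nrow(met), 9L)
  # planted layout: clone0 peripheral, clone2 central, in every replicate
  expect_true(all(met$position_class[met$clone == "clone0"] == "peripheral"))
  expect_true(all(met$position_class[met$clone == "clone2"] == "central"))
  # annular clones aggregate: positive, significant Moran's I
  expect_true(all(met$morans_I[met$clone != "clone1"] > 0))
  expect_true(all(met$perm_p[met$clone != "clone1"] <= 0.05))
  cmp <- compare_clones_across_replicates(met)
  row <- cmp[cmp$clone_a == "clone0" & cmp$clone_b == "clone2", ]
  expect_equal(row$df, 2L)
  expect_lt(row$p, 0.05)
  expect_lt(row$t, 0)   # peripheral clone has smaller boundary distances
})

test_that("paired comparisons flag zero-variance differences", {
  met <- data.frame(replicate_id = rep(c("r1", "r2"), each = 2),
                    clone = rep(c("a", "b"), 2),
                    mean_boundary_distance = c(1, 2, 2, 3))
  cmp <- compare_clones_across_replicates(met)
  expect_true(is.na(cmp$p))
  expect_match(cmp$note, "zero-variance")
})

test_that("clone labels attach to spots by barcode with an inner join", {
  spots <- make_spots(1:3, 1:3)
  labels <- c(s001 = "clone0", s003 = "clone1", zzz = "clone9")
  out <- attach_clone_labels(spots, labels)
  expect_equal(out$clone, c("clone0", NA, "clone1"))
  expect_equal(attr(out, "n_matched"), 2L)
  expect_error(attach_clone_labels(spots, c(q = "clone0")), "no spot barcode")
})
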