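# Shared fixtures and small constructors for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

# The benchmark simulation: 500 cells, 3 clones, 10 informative among 90
# noise variants, mean depth 30. Computed once per test run.
default_sim <- function() {
  if (is.null(.cache$sim)) {
    cfg <- generator_config(seed = 20260101L)
    sim <- simulate_clonal_population(cfg)
    bc <- simulate_barcoding(sim$truth, cfg)
    .cache$sim <- list(cfg = cfg, acm = sim$acm, truth = bc$truth,
                       barcodes = bc$barcodes, annotation = bc$annotation)
  }
  .cache$sim
}

# Variant scores for the benchmark simulation (the expensive step).
default_scores <- function() {
  if (is.null(.cache$scores)) {
    sim <- default_sim()
    sc <- score_variants(apply_cell_filters(sim$acm), seed = 99L)
    .cache$scores <- select_informative(sc)
  }
  .cache$scores
}

make_acm <- function(AD, DP) {
  AD <- as.matrix(AD); DP <- as.matrix(DP)
  allele_count_matrix(AD, DP,
                      sprintf("cell%03d", seq_len(nrow(AD))),
                      sprintf("%d%s>%s", seq_len(ncol(AD)) + 100L, "C", "T"))
}

true_label_vector <- function(truth) {
  stats::setNames(paste0("clone", truth$clone_of_cell),
                  names(truth$clone_of_cell))
}

# Rook-adjacency weight matrix of an nr x nc grid (row-major spot order).
rook_grid_weights <- function(nr, nc) {
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  n <- nrow(g)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(g$r[i] - g$r[j]) + abs(g$c[i] - g$c[j]) == 1L) W[i, j] <- 1
  }
  Matrix::Matrix(W, sparse = TRUE)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
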