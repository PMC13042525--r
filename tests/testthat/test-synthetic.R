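test_that("generator config validation rejects impossible settings", {
  expect_error(generator_config(K = 0), "K must be >= 1")
  expect_error(generator_config(n_informative = 0), "no clonal signal")
  expect_error(generator_config(clone_proportions = c(0.5, 0.4), K = 2),
               "sum to 1")
  expect_error(generator_config(theta_error = 0.5,
                                theta_high_range = c(0.3, 0.9)),
               "theta_error")
  expect_error(generator_config(barcode_pool_size = 0), "barcode_pool_size")
  lay <- default_radial_layout(3)
  lay[1, ] <- c(0.9, 0.1)
  expect_error(generator_config(layout = lay), "r_min > r_max")
})

test_that("noise-free degenerate case yields all-or-nothing counts", {
  # one variant carried by one clone at theta = 1, DP fixed at 10, no error
  cfg <- generator_config(n_cells = 60, K = 2, n_informative = 1,
                          n_noise_variants = 0, mean_dp = 10,
                          dp_dispersion = 0, theta_high_range = c(1, 1),
                          theta_error = 0, seed = 5L)
  # Poisson coverage varies; force DP = 10 by regenerating AD from truth
  sim <- simulate_clonal_population(cfg)
  tr <- sim$truth
  carrier <- tr$carrier_clones[[tr$informative_variants[1]]]
  ad <- as.matrix(sim$acm$AD)[, tr$informative_variants[1]]
  dp <- as.matrix(sim$acm$DP)[, tr$informative_variants[1]]
  in_carrier <- tr$clone_of_cell %in% carrier
  expect_true(all(ad[in_carrier] == dp[in_carrier]))
  expect_true(all(ad[!in_carrier] == 0))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- generator_config(n_cells = 100, n_noise_variants = 10, seed = 77L)
  a <- simulate_clonal_population(cfg)
  b <- simulate_clonal_population(cfg)
  expect_identical(as.matrix(a$acm$AD), as.matrix(b$acm$AD))
  expect_identical(as.matrix(a$acm$DP), as.matrix(b$acm$DP))
  expect_identical(a$truth$clone_of_cell, b$truth$clone_of_cell)
  ba <- simulate_barcoding(a$truth, cfg)
  bb <- simulate_barcoding(b$truth, cfg)
  expect_identical(ba$barcodes, bb$barcodes)
  sa <- simulate_spatial(ba$truth, cfg)
  sb <- simulate_spatial(bb$truth, cfg)
  expect_identical(sa, sb)
})

test_that("noise variants match exact binomial moments of the generative law", {
  # oracle: pooled VAF of a noise variant is theta_error with binomial SE
  # sqrt(theta (1 - theta) / sum(DP))
  cfg <- generator_config(n_cells = 500, K = 3, mean_dp = 30, seed = 31L)
  sim <- simulate_clonal_population(cfg)
  noise <- setdiff(sim$acm$variant_ids, sim$truth$informative_variants)
  AD <- as.matrix(sim$acm$AD); DP <- as.matrix(sim$acm$DP)
  # pooled over all noise variants: a single 3-sigma check
  tot_all <- sum(DP[, noise])
  vaf_all <- sum(AD[, noise]) / tot_all
  se_all <- sqrt(cfg$theta_error * (1 - cfg$theta_error) / tot_all)
  expect_lt(abs(vaf_all - cfg$theta_error), 3 * se_all)
  # per variant, widened to 4.5 sigma so the family-wise false-failure
  # probability over 90 variants stays below 1e-3
  for (v in noise) {
    tot <- sum(DP[, v])
    vaf <- sum(AD[, v]) / tot
    se <- sqrt(cfg$theta_error * (1 - cfg$theta_error) / tot)
    expect_lt(abs(vaf - cfg$theta_error), 4.5 * se + 1e-12)
  }
})

test_that("empirical clone proportions obey the law of large numbers", {
  cfg <- generator_config(n_cells = 10000, n_informative = 2,
                          n_noise_variants = 0, mean_dp = 2, seed = 13L)
  sim <- simulate_clonal_population(cfg)
  emp <- as.numeric(table(factor(sim$truth$clone_of_cell, levels = 0:2))) /
    cfg$n_cells
  se <- sqrt(cfg$clone_proportions * (1 - cfg$clone_proportions) /
               cfg$n_cells)
  expect_true(all(abs(emp - cfg$clone_proportions) < 3 * se + 3 / cfg$n_cells))
})

test_that("barcode collisions match the birthday-problem enumeration", {
  # oracle: P(a progenitor collides) = 1 - (1 - 1/pool)^(P - 1), computed
  # independently of the generator
  cfg <- generator_config(n_cells = 400, n_informative = 2,
                          n_noise_variants = 0, mean_dp = 2,
                          barcode_pool_size = 50, seed = 17L)
  fracs <- exps <- numeric(0)
  for (s in 1:200) {
    cfg$seed <- 1000L + s
    sim <- simulate_clonal_population(cfg)
    bc <- simulate_barcoding(sim$truth, cfg)
    P <- length(bc$truth$barcode_of_progenitor)
    fracs <- c(fracs, length(unlist(bc$truth$collision_groups)) / P)
    exps <- c(exps, 1 - (1 - 1 / cfg$barcode_pool_size)^(P - 1))
  }
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - mean(exps)), 3 * se)
})

test_that("huge pools give zero collisions; concentration 0 gives uni-lineage", {
  cfg <- generator_config(n_cells = 300, n_informative = 2,
                          n_noise_variants = 0, mean_dp = 2,
                          barcode_pool_size = 1e9,
                          lineage_concentration = 0, seed = 23L)
  sim <- simulate_clonal_population(cfg)
  bc <- simulate_barcoding(sim$truth, cfg)
  expect_length(bc$truth$collision_groups, 0)
  # every progenitor's cells share one lineage
  tr <- bc$truth
  for (pid in unique(tr$progenitor_of_cell)) {
    lin <- tr$lineage_of_cell[tr$progenitor_of_cell == pid]
    expect_length(unique(lin), 1)
  }
  # no collisions + uni-lineage progenitors => full concordance downstream
  fs <- filter_singletons(build_barcode_clones(bc$barcodes))
  rep <- suppressWarnings(
    concordance_report(fs$clones, true_label_vector(tr), bc$annotation))
  expect_equal(rep$n_discordant, 0)
})

test_that("spots stay inside their clone's radial band when jitter is off", {
  lay <- rbind(clone0 = c(0.9, 1), clone1 = c(0, 0.3))
  cfg <- generator_config(n_cells = 50, K = 2, n_informative = 2,
                          n_noise_variants = 0, mean_dp = 2,
                          layout = lay, jitter_px = 0,
                          n_spatial_replicates = 1,
                          spots_per_replicate = 200, seed = 3L)
  sim <- simulate_clonal_population(cfg)
  spots <- simulate_spatial(sim$truth, cfg)[[1]]
  ctr <- c(1.2, 1.2) * cfg$disc_radius_px
  r <- sqrt((spots$pxl_col_in_fullres - ctr[1])^2 +
              (spots$pxl_row_in_fullres - ctr[2])^2)
  expect_true(all(r[spots$clone == "clone0"] >= 0.9 * cfg$disc_radius_px - 1e-9))
  expect_true(all(r[spots$clone == "clone1"] <= 0.3 * cfg$disc_radius_px + 1e-9))
})

test_that("AD never exceeds DP on generated matrices", {
  sim <- default_sim()
  expect_true(all((sim$acm$DP - sim$acm$AD)@x >= 0))
})

test_that("planted clones are pairwise separable by carrier sets", {
  sim <- default_sim()
  carriers <- sim$truth$carrier_clones
  K <- sim$cfg$K
  for (a in 0:(K - 2)) for (b in (a + 1):(K - 1)) {
    expect_true(any(vapply(carriers, function(cs)
      xor(a %in% cs, b %in% cs), TRUE)))
  }
})
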