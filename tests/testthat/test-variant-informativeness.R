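# Brute-force grid oracle for the two-component binomial mixture: maximize
# the same log-likelihood over a dense (theta1 <= theta2, pi) grid.
grid_mixture_loglik <- function(ad, dp, theta_step = 0.005, pi_step = 0.05) {
  th <- seq(theta_step, 1 - theta_step, by = theta_step)
  pis <- seq(pi_step, 1 - pi_step, by = pi_step)
  E <- outer(seq_along(ad), seq_along(th),
             function(i, j) stats::dbinom(ad[i], dp[i], th[j]))
  best <- -Inf
  for (i in seq_along(th)) {
    for (j in i:length(th)) {
      mix <- E[, i] %o% pis + E[, j] %o% (1 - pis)
      best <- max(best, max(colSums(log(mix))))
    }
  }
  best
}

test_that("filter settings reject inconsistent fractions", {
  expect_error(filter_config(maf_min = 1.5), "\\[0, 1\\]")
  expect_error(filter_config(prevalence_lower = 0.96),
               "prevalence_lower must be below")
})

test_that("cell filtering keeps exactly the cells with a usable observation", {
  # cell 1: AD 1 / DP 2 (usable); cell 2: AD 1 / DP 1 (DP below threshold);
  # cell 3: AD 0 / DP 30 (no alternate allele)
  acm <- make_acm(matrix(c(1, 1, 0), 3), matrix(c(2, 1, 30), 3))
  kept <- apply_cell_filters(acm, filter_config())
  expect_equal(kept$cell_ids, "cell001")
  acm2 <- make_acm(matrix(0, 2, 1), matrix(5, 2, 1))
  expect_error(apply_cell_filters(acm2), "no cells survive")
})

test_that("each variant-exclusion rule fires on its hand-built exemplar", {
  n <- 20L
  # columns: keep, quasi-germline, too-rare, low-maf, low-aggregated-count
  AD <- cbind(c(rep(5, 10), rep(0, 10)),   # half the cells at VAF 0.5
              rep(9, n),                   # VAF 0.9 in every cell
              rep(0, n),                   # never above the AF threshold
              c(rep(1, 10), rep(0, 10)),   # pooled AF 0.05 < 0.1
              c(rep(1, 4), rep(0, 16)))    # pooled AD 4 < 5 at MAF 0.1
  DP <- cbind(matrix(10, n, 4), c(rep(4, 10), rep(0, 10)))
  acm <- make_acm(AD, DP)
  res <- apply_variant_filters(acm, filter_config())
  expect_equal(res$acm$variant_ids, "101C>T")
  expect_equal(res$excluded$rule[match(c("102C>T", "103C>T", "104C>T",
                                         "105C>T"), res$excluded$variant)],
               c("quasi_germline", "too_rare", "low_maf",
                 "low_aggregated_count"))
})

test_that("the single-binomial closed form is the true maximizer", {
  ad <- c(3, 0, 7, 2); dp <- c(10, 5, 20, 8)
  f <- fit_single_binomial(ad, dp)
  expect_equal(f$theta_hat, sum(ad) / sum(dp))
  opt <- stats::optimize(function(t)
    sum(stats::dbinom(ad, dp, t, log = TRUE)), c(1e-6, 1 - 1e-6),
    maximum = TRUE)
  expect_lte(opt$objective, f$loglik1 + 1e-8)
  expect_error(fit_single_binomial(0, 0), "no cell has coverage")
})

test_that("the mixture EM matches a dense grid-search oracle", {
  set.seed(42)
  n <- 40L
  dp <- rpois(n, 20) + 1L
  comp <- rbinom(n, 1, 0.5)
  ad <- rbinom(n, dp, ifelse(comp == 1, 0.6, 0.02))
  fit <- fit_two_binomial_mixture(ad, dp, seed = 7L)
  # the grid oracle uses dbinom, so it already includes the binomial
  # coefficients the EM carries in `const`
  oracle <- grid_mixture_loglik(ad, dp)
  # EM must do at least as well as the grid, and cannot exceed it by more
  # than the grid's discretization error
  expect_gte(fit$loglik2, oracle - 1e-3)
  expect_lte(fit$loglik2, oracle + 0.5)
  expect_lt(fit$theta1, 0.1)
  expect_gt(fit$theta2, 0.4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik2)))
})

test_that("the mixture never scores below the nested single fit", {
  cases <- list(list(ad = rep(0L, 10), dp = rep(8L, 10)),       # all zero
                list(ad = rep(8L, 10), dp = rep(8L, 10)),       # all fixed
                list(ad = c(0L, 8L), dp = c(8L, 8L)))           # two cells
  for (cs in cases) {
    f1 <- fit_single_binomial(cs$ad, cs$dp)
    f2 <- fit_two_binomial_mixture(cs$ad, cs$dp, seed = 3L)
    expect_gte(f2$loglik2, f1$loglik1 - 1e-9)
  }
})

test_that("delta-BIC penalizes the two extra mixture parameters", {
  # hand-computed: (1*log(n) - 2*ll1) - (3*log(n) - 2*ll2)
  expect_equal(delta_bic(-100, -90, 50), 2 * (-90 + 100) - 2 * log(50))
  # equal likelihoods must give a strictly negative score for n_eff > 1
  expect_lt(delta_bic(-50, -50, 10), 0)
})

test_that("variant scoring is deterministic under a fixed seed", {
  sim <- default_sim()
  sub <- sim$acm[1:60, 1:8]
  a <- score_variants(sub, seed = 5L)
  b <- score_variants(sub, seed = 5L)
  expect_identical(a, b)
})

test_that("knee selection cuts a hand-built curve at the planted knee", {
  # three strong scores, seven near-zero: the cumulative curve's knee sits
  # at index 3 and exactly the strong scores are selected
  db <- c(0.01, 100, 0.012, 90, 0.009, 80, 0.011, 0.008, 0.01, 0.013)
  scores <- data.frame(variant = sprintf("%dC>T", 1:10 * 10), delta_bic = db)
  sel <- select_informative(scores)
  expect_equal(attr(sel, "knee"), 3L)
  expect_equal(sort(scores$variant[sel$selected]),
               sort(scores$variant[db > 1]))
  # negative scores inside the knee are still rejected
  db2 <- c(100, 90, -80, rep(0.01, 7))
  scores2 <- data.frame(variant = sprintf("%dC>T", 1:10 * 10),
                        delta_bic = db2)
  sel2 <- select_informative(scores2)
  expect_false(any(sel2$selected & sel2$delta_bic < 0))
})

test_that("a flat curve falls back to the positive-score set with a warning", {
  scores <- data.frame(variant = sprintf("%dC>T", 1:5 * 10),
                       delta_bic = rep(2, 5))
  expect_warning(sel <- select_informative(scores), "flat delta-BIC")
  expect_true(all(sel$selected))
  scores0 <- data.frame(variant = sprintf("%dC>T", 1:5 * 10),
                        delta_bic = rep(-1, 5))
  expect_warning(
    expect_warning(sel0 <- select_informative(scores0), "flat delta-BIC"),
    "selection is empty")
  expect_false(any(sel0$selected))
})

test_that("selection recovers the planted informative variants", {
  sim <- default_sim()
  sel <- default_scores()
  chosen <- sel$variant[sel$selected]
  truth <- sim$truth$informative_variants
  expect_true(all(truth %in% chosen))
  expect_equal(length(setdiff(chosen, truth)), 0L)
  # noise variants overwhelmingly score negative
  noise <- setdiff(sel$variant, truth)
  expect_gt(mean(sel$delta_bic[sel$variant %in% noise] < 0), 0.95)
})
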