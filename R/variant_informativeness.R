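# Scoring mitochondrial variants for clonal informativeness.
#
# A clone-informative variant has a bimodal per-cell VAF distribution: high
# heteroplasmy in carrier clones, background error elsewhere. Each variant
# is scored by the BIC difference between a single-binomial fit and a
# two-component binomial mixture fit; the informative set is cut at a knee
# point of the sorted cumulative delta-BIC curve.

#' Cell- and variant-level filter settings
#'
#' @param min_cell_dp Minimum coverage for a variant observation to count
#'   toward keeping a cell (a cell is retained if it has at least one
#'   variant with `DP >= min_cell_dp` and `AD >= min_cell_ad`).
#' @param min_cell_ad Minimum alternate depth for the same rule.
#' @param maf_min Minimum pooled minor-allele fraction of a variant.
#' @param min_aggregated_count Minimum total alternate count of a variant.
#' @param prevalence_upper Variants whose per-cell VAF exceeds
#'   `prevalence_af` in at least this fraction of covered cells are
#'   excluded as quasi-germline.
#' @param prevalence_lower Variants exceeding `prevalence_af` in fewer than
#'   this fraction of covered cells are excluded as too rare.
#' @param prevalence_af VAF threshold used by the two prevalence rules.
#' @return A list of class `FilterConfig`.
#' @export
filter_config <- function(min_cell_dp = 2L, min_cell_ad = 1L,
                          maf_min = 0.1, min_aggregated_count = 5L,
                          prevalence_upper = 0.95, prevalence_lower = 0.05,
                          prevalence_af = 0.05) {
  fr <- c(maf_min = maf_min, prevalence_upper = prevalence_upper,
          prevalence_lower = prevalence_lower, prevalence_af = prevalence_af)
  if (any(fr < 0 | fr > 1)) stop("filter fractions must lie in [0, 1]")
  if (prevalence_lower >= prevalence_upper)
    stop("prevalence_lower must be below prevalence_upper")
  structure(list(min_cell_dp = as.integer(min_cell_dp),
                 min_cell_ad = as.integer(min_cell_ad),
                 maf_min = maf_min,
                 min_aggregated_count = as.integer(min_aggregated_count),
                 prevalence_upper = prevalence_upper,
                 prevalence_lower = prevalence_lower,
                 prevalence_af = prevalence_af),
            class = "FilterConfig")
}

#' Drop cells that carry no usable variant observation
#'
#' Retains exactly the cells having at least one variant with coverage
#' `DP >= min_cell_dp` and an alternate allele (`AD >= min_cell_ad`);
#' cell order is preserved.
#'
#' @param acm An [allele_count_matrix()].
#' @param cfg A [filter_config()].
#' @return The filtered `AlleleCountMatrix`.
#' @export
apply_cell_filters <- function(acm, cfg = filter_config()) {
  ok <- (acm$DP >= cfg$min_cell_dp) & (acm$AD >= cfg$min_cell_ad)
  keep <- Matrix::rowSums(ok) > 0
  if (!any(keep))
    stop("no cells survive filtering (min_cell_dp = ", cfg$min_cell_dp,
         ", min_cell_ad = ", cfg$min_cell_ad, ")")
  acm[which(keep), ]
}

#' Exclude quasi-germline, rare and low-signal variants
#'
#' Applies, in sequence: (1) the upper prevalence rule -- a variant whose
#' per-cell VAF exceeds `prevalence_af` in at least `prevalence_upper` of
#' its covered cells is quasi-germline, hence clonally uninformative;
#' (2) the lower prevalence rule -- a variant exceeding that VAF in fewer
#' than `prevalence_lower` of covered cells is too rare; (3) the pooled
#' minor-allele-fraction and aggregated-count rules.
#'
#' @inheritParams apply_cell_filters
#' @return A list with `acm` (surviving variants) and `excluded`, a
#'   data.frame naming every excluded variant and the rule that fired.
#' @export
apply_variant_filters <- function(acm, cfg = filter_config()) {
  DP <- acm$DP; AD <- acm$AD
  covered <- DP > 0
  n_cov <- Matrix::colSums(covered)
  above <- (AD > cfg$prevalence_af * DP) & covered
  n_above <- Matrix::colSums(above)
  frac_above <- ifelse(n_cov > 0, n_above / n_cov, 0)
  pooled_ad <- Matrix::colSums(AD)
  pooled_dp <- Matrix::colSums(DP)
  pooled_af <- ifelse(pooled_dp > 0, pooled_ad / pooled_dp, 0)
  pooled_maf <- pmin(pooled_af, 1 - pooled_af)

  rule <- rep(NA_character_, length(acm$variant_ids))
  rule[frac_above >= cfg$prevalence_upper] <- "quasi_germline"
  r2 <- is.na(rule) & frac_above < cfg$prevalence_lower
  rule[r2] <- "too_rare"
  r3 <- is.na(rule) & pooled_maf < cfg$maf_min
  rule[r3] <- "low_maf"
  r4 <- is.na(rule) & pooled_ad < cfg$min_aggregated_count
  rule[r4] <- "low_aggregated_count"

  keep <- is.na(rule)
  excluded <- data.frame(variant = acm$variant_ids[!keep],
                         rule = rule[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    warning("no variants survive filtering")
  list(acm = acm[, which(keep)], excluded = excluded)
}

#' Fit a single binomial to one variant's counts
#'
#' Closed form: `theta_hat = sum(AD) / sum(DP)` over covered cells,
#' clamped to `[1e-6, 1 - 1e-6]` -- the same parameter space the mixture
#' EM works in -- so the mixture log-likelihood genuinely nests this fit.
#'
#' @param ad,dp Integer vectors over cells (only `dp > 0` entries carry
#'   likelihood).
#' @return List with `theta_hat` and `loglik1`.
#' @export
fit_single_binomial <- function(ad, dp) {
  keep <- dp > 0
  if (!any(keep)) stop("no cell has coverage for this variant")
  ad <- ad[keep]; dp <- dp[keep]
  theta <- clamp01(sum(ad) / sum(dp))
  list(theta_hat = theta, loglik1 = sum(stats::dbinom(ad, dp, theta, log = TRUE)))
}

#' Fit a two-component binomial mixture by EM
#'
#' Maximizes `sum_c log(pi * Binom(ad_c; dp_c, theta1) + (1 - pi) *
#' Binom(ad_c; dp_c, theta2))` over multiple restarts. Components are
#' initialized from quantiles of the per-cell VAF plus jitter; one restart
#' always starts from the collapsed single-binomial solution so the mixture
#' log-likelihood can never fall below the nested single fit. Thetas are
#' clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param ad,dp Integer count vectors over cells.
#' @param restarts Number of EM initializations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap; non-convergence returns the best solution
#'   so far with `converged = FALSE`, never an error.
#' @param seed Optional seed for the jittered initializations.
#' @return List with `theta1 <= theta2`, `pi_mix` (weight on `theta1`),
#'   `loglik2`, `converged`, and `loglik_trace` (per-iteration
#'   log-likelihood of the best restart).
#' @export
fit_two_binomial_mixture <- function(ad, dp, restarts = 5L, tol = 1e-6,
                                     max_iter = 500L, seed = NULL) {
  keep <- dp > 0
  if (sum(keep) < 2L) stop("need at least 2 covered cells for a mixture fit")
  ad <- ad[keep]; dp <- dp[keep]
  vaf <- ad / dp
  theta_hat <- sum(ad) / sum(dp)
  with_seed(seed, {
    qs <- stats::quantile(vaf, c(0.1, 0.9), names = FALSE)
    inits <- list(c(theta_hat, theta_hat))  # collapsed: nests the single fit
    for (r in seq_len(max(restarts - 1L, 1L))) {
      jit <- stats::runif(2, -0.05, 0.05)
      inits[[r + 1L]] <- clamp01(sort(qs + jit))
    }
    best <- NULL
    for (init in inits) {
      fit <- em_binom_mixture(ad, dp, init[1L], init[2L], 0.5, tol, max_iter)
      if (is.null(best) || fit$loglik2 > best$loglik2) best <- fit
    }
    best
  })
}

em_binom_mixture <- function(ad, dp, t1, t2, pi1, tol, max_iter) {
  t1 <- clamp01(t1); t2 <- clamp01(t2)
  const <- sum(lchoose(dp, ad))
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(pi1) + ad * log(t1) + (dp - ad) * log1p(-t1)
    l2 <- log(1 - pi1) + ad * log(t2) + (dp - ad) * log1p(-t2)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(lse) + const
    trace <- c(trace, ll)
    g1 <- exp(l1 - lse)
    pi1 <- mean(g1)
    pi1 <- min(max(pi1, 1e-9), 1 - 1e-9)
    t1 <- clamp01(sum(g1 * ad) / max(sum(g1 * dp), .Machine$double.eps))
    t2 <- clamp01(sum((1 - g1) * ad) / max(sum((1 - g1) * dp), .Machine$double.eps))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (t1 > t2) {
    tmp <- t1; t1 <- t2; t2 <- tmp
    pi1 <- 1 - pi1
  }
  list(theta1 = t1, theta2 = t2, pi_mix = pi1,
       loglik2 = trace[length(trace)], converged = converged,
       loglik_trace = trace)
}

#' Delta-BIC of the two- versus one-component fit
#'
#' `BIC_m = p_m * log(n_eff) - 2 * loglik_m` with one free parameter for
#' the single binomial and three for the mixture; the score is
#' `BIC_1 - BIC_2`, so larger values give stronger support for two VAF
#' components, i.e. clonal informativeness. `n_eff` counts cells with
#' coverage, because cells without reads carry no likelihood.
#'
#' @param loglik1,loglik2 Maximized log-likelihoods of the two fits.
#' @param n_eff Number of cells with `DP > 0`.
#' @return The delta-BIC score.
#' @export
delta_bic <- function(loglik1, loglik2, n_eff) {
  (1 * log(n_eff) - 2 * loglik1) - (3 * log(n_eff) - 2 * loglik2)
}

#' Score every variant of a matrix for clonal informativeness
#'
#' Runs the single-binomial and two-component mixture fits per variant and
#' computes the delta-BIC score. Variants with fewer than 2 covered cells
#' get `NA` scores.
#'
#' @param acm An [allele_count_matrix()] (typically after
#'   [apply_cell_filters()] / [apply_variant_filters()]).
#' @param restarts,tol,max_iter EM settings, see
#'   [fit_two_binomial_mixture()].
#' @param seed Seed; each variant derives its own sub-stream.
#' @return A data.frame with one row per variant: `variant`, `theta_hat`,
#'   `theta1`, `theta2`, `pi_mix`, `loglik1`, `loglik2`, `delta_bic`,
#'   `n_eff`, `converged`.
#' @export
score_variants <- function(acm, restarts = 5L, tol = 1e-6, max_iter = 500L,
                           seed = 1L) {
  AD <- as.matrix(acm$AD); DP <- as.matrix(acm$DP)
  res <- lapply(seq_along(acm$variant_ids), function(v) {
    ad <- AD[, v]; dp <- DP[, v]
    n_eff <- sum(dp > 0)
    if (n_eff < 2L)
      return(data.frame(variant = acm$variant_ids[v], theta_hat = NA_real_,
                        theta1 = NA_real_, theta2 = NA_real_,
                        pi_mix = NA_real_, loglik1 = NA_real_,
                        loglik2 = NA_real_, delta_bic = NA_real_,
                        n_eff = n_eff, converged = NA))
    f1 <- fit_single_binomial(ad, dp)
    f2 <- fit_two_binomial_mixture(ad, dp, restarts, tol, max_iter,
                                   seed = derive_seed(seed, v))
    data.frame(variant = acm$variant_ids[v], theta_hat = f1$theta_hat,
               theta1 = f2$theta1, theta2 = f2$theta2, pi_mix = f2$pi_mix,
               loglik1 = f1$loglik1, loglik2 = f2$loglik2,
               delta_bic = delta_bic(f1$loglik1, f2$loglik2, n_eff),
               n_eff = n_eff, converged = f2$converged)
  })
  do.call(rbind, res)
}

#' Select informative variants at the knee of the cumulative delta-BIC curve
#'
#' Scores are sorted in decreasing order (ties broken by ascending
#' mitochondrial position for determinism) and accumulated; the knee is the
#' index maximizing the perpendicular distance to the chord joining the
#' cumulative curve's endpoints. Variants up to the knee, intersected with
#' `{delta_bic > 0}`, are selected. A flat curve has no knee and falls back
#' to the positive-score set.
#'
#' @param scores A data.frame from [score_variants()] (needs columns
#'   `variant` and `delta_bic`).
#' @return The input with logical column `selected` added, plus attributes
#'   `knee` (index on the sorted curve, or `NA`) and `order` (sorted
#'   variant ids).
#' @export
select_informative <- function(scores) {
  stopifnot(nrow(scores) >= 3L)
  db <- scores$delta_bic
  pos <- suppressWarnings(parse_variant_id(scores$variant)$position)
  ord <- order(-db, pos)
  y <- cumsum(db[ord])
  n <- length(y)
  x <- seq_len(n)
  chord <- c(x[n] - x[1L], y[n] - y[1L])
  selected_sorted <- logical(n)
  if (all(abs(db - db[1L]) < 1e-12) || all(!is.finite(y))) {
    knee <- NA_integer_
    warning("flat delta-BIC curve: no knee, selecting positive scores only")
    selected_sorted <- db[ord] > 0
  } else {
    d <- abs(chord[2L] * (x - x[1L]) - chord[1L] * (y - y[1L])) /
      sqrt(sum(chord^2))
    knee <- which.max(d)
    selected_sorted[seq_len(knee)] <- db[ord][seq_len(knee)] > 0
  }
  if (!any(selected_sorted))
    warning("no variant has positive delta-BIC; selection is empty")
  scores$selected <- FALSE
  scores$selected[ord] <- selected_sorted
  attr(scores, "knee") <- knee
  attr(scores, "order") <- scores$variant[ord]
  scores
}
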