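# Assigning cells to mitochondrial clones with a K-component binomial
# mixture over the informative variants.

#' Fit a K-clone binomial mixture to an allele-count matrix
#'
#' Each clone k is a vector of allele frequencies theta[k, v] over the
#' informative variants; cell c belongs to clone k with responsibility
#' gamma[c, k] proportional to `pi_k * prod_v Binom(AD_cv; DP_cv,
#' theta_kv)` (computed in the log domain). The M-step re-estimates each
#' theta with symmetric pseudocounts `a0` to keep frequencies off the 0/1
#' boundaries, and `pi_k` as the mean responsibility. The best of several
#' seeded restarts is returned with clones re-ordered canonically
#' (descending mixing weight, then lexicographic theta) so repeated runs
#' produce identical reports.
#'
#' @param acm An [allele_count_matrix()] restricted to the selected
#'   informative variants.
#' @param K Number of clones (>= 1).
#' @param restarts,tol,max_iter EM settings.
#' @param pseudocount Symmetric Beta pseudocount `a0 = b0` on every theta.
#' @param min_prob Responsibility threshold below which a cell is left
#'   `"unassigned"`.
#' @param seed Integer seed for the restarts.
#' @return A `CloneModel` list: `K`, `theta` (K x V), `pi`, `gamma`
#'   (cell x K), `labels` (per-cell `"clone<k>"` or `"unassigned"`),
#'   `loglik`, `loglik_trace`, `objective_trace` (penalized EM objective),
#'   `converged`, `min_prob`, `cell_ids`, `variant_ids`.
#' @export
fit_clone_mixture <- function(acm, K, restarts = 5L, tol = 1e-6,
                              max_iter = 500L, pseudocount = 0.2,
                              min_prob = 0.8, seed = 1L) {
  K <- as.integer(K)
  n <- length(acm$cell_ids)
  V <- length(acm$variant_ids)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of cells (", n, ")")
  if (V == 0L) stop("no informative variants to fit on")
  AD <- as.matrix(acm$AD)
  DP <- as.matrix(acm$DP)
  RD <- DP - AD
  const <- sum(lchoose(DP, AD))
  vaf <- AD / pmax(DP, 1)

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(derive_seed(seed, r), {
      # centre theta on the VAF of K randomly chosen distinct cells
      centres <- sample.int(n, K)
      clamp01(vaf[centres, , drop = FALSE] +
                matrix(stats::runif(K * V, -0.05, 0.05), K, V))
    })
    fit <- em_clone_mixture(AD, RD, init, rep(1 / K, K), tol, max_iter,
                            pseudocount, const)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(-best$pi, apply(best$theta, 1L, function(t)
    paste(sprintf("%.6f", t), collapse = ",")))
  model <- list(K = K,
                theta = best$theta[ord, , drop = FALSE],
                pi = best$pi[ord],
                gamma = best$gamma[, ord, drop = FALSE],
                loglik = best$loglik,
                loglik_trace = best$loglik_trace,
                objective_trace = best$objective_trace,
                converged = best$converged,
                min_prob = min_prob,
                cell_ids = acm$cell_ids,
                variant_ids = acm$variant_ids)
  rownames(model$theta) <- names(model$pi) <- colnames(model$gamma) <-
    paste0("clone", seq_len(K) - 1L)
  rownames(model$gamma) <- acm$cell_ids
  colnames(model$theta) <- acm$variant_ids
  model$labels <- assign_clones(model, min_prob)
  class(model) <- "CloneModel"
  model
}

em_clone_mixture <- function(AD, RD, theta, pi_k, tol, max_iter,
                             a0, const) {
  K <- nrow(theta)
  ll_old <- -Inf
  trace <- obj_trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  for (it in seq_len(max_iter)) {
    lg <- AD %*% t(log(theta)) + RD %*% t(log1p(-theta))
    lg <- sweep(lg, 2L, log(pi_k), `+`)
    lse <- row_logsumexp(lg)
    ll <- sum(lse) + const
    prior <- a0 * sum(log(theta) + log1p(-theta))
    trace <- c(trace, ll)
    obj_trace <- c(obj_trace, ll + prior)
    gamma <- exp(lg - lse)
    pi_k <- colMeans(gamma)
    pi_k <- pi_k / sum(pi_k)
    num <- t(gamma) %*% AD + a0
    den <- t(gamma) %*% (AD + RD) + 2 * a0
    theta <- clamp01(as.matrix(num / den))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(theta = theta, pi = pi_k, gamma = gamma,
       loglik = trace[length(trace)], loglik_trace = trace,
       objective_trace = obj_trace, converged = converged)
}

#' @method print CloneModel
#' @export
print.CloneModel <- function(x, ...) {
  cat("CloneModel: K =", x$K, "over", length(x$variant_ids),
      "variants,", length(x$cell_ids), "cells\n")
  cat("  mixing weights:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  cat("  unassigned:", sum(x$labels == "unassigned"), "cells (min_prob =",
      x$min_prob, ")\n")
  invisible(x)
}

#' MAP clone assignment with a confidence threshold
#'
#' @param model A fitted `CloneModel`.
#' @param min_prob Cells whose maximum responsibility falls below this are
#'   labelled `"unassigned"`.
#' @return Character vector of per-cell labels, named by cell id.
#' @export
assign_clones <- function(model, min_prob = model$min_prob) {
  mx <- apply(model$gamma, 1L, max)
  k <- apply(model$gamma, 1L, which.max)
  labels <- colnames(model$gamma)[k]
  labels[mx < min_prob] <- "unassigned"
  stats::setNames(labels, rownames(model$gamma))
}

#' Scan candidate clone numbers and pick an elbow
#'
#' Fits the clone mixture for each K in `k_min:k_max` and recommends the
#' largest K whose log-likelihood gain over K - 1 exceeds
#' `gain_threshold` times the K = 1 to 2 gain and whose clones all have
#' pairwise-distinct allele-frequency profiles (max absolute theta
#' difference above `theta_sep`). A flat curve recommends `k_min`.
#'
#' @inheritParams fit_clone_mixture
#' @param k_min,k_max Range of clone numbers to scan.
#' @param gain_threshold Relative gain defining the elbow.
#' @param theta_sep Minimum max-abs difference between two clones' theta
#'   rows for them to count as distinct.
#' @return A list of class `KScanReport`: `table` (data.frame with `K`,
#'   `loglik`, `bic`, `gain`, `distinct_profiles`, `eligible`),
#'   `recommended_K`, and `models` (the fitted `CloneModel`s, named by K).
#' @export
scan_k <- function(acm, k_min = 1L, k_max = 6L, restarts = 3L, tol = 1e-6,
                   max_iter = 300L, pseudocount = 0.2, min_prob = 0.8,
                   gain_threshold = 0.02, theta_sep = 0.1, seed = 1L) {
  stopifnot(k_min >= 1L, k_max >= k_min)
  ks <- k_min:k_max
  n <- length(acm$cell_ids)
  V <- length(acm$variant_ids)
  models <- lapply(ks, function(K)
    fit_clone_mixture(acm, K, restarts = restarts, tol = tol,
                      max_iter = max_iter, pseudocount = pseudocount,
                      min_prob = min_prob, seed = derive_seed(seed, K)))
  names(models) <- as.character(ks)
  ll <- vapply(models, `[[`, 0, "loglik")
  n_par <- ks * V + (ks - 1L)
  bic <- n_par * log(n) - 2 * ll
  gain <- c(NA_real_, diff(ll))
  distinct <- vapply(models, function(m) {
    if (m$K == 1L) return(TRUE)
    th <- m$theta
    for (a in seq_len(m$K - 1L)) for (b in seq(a + 1L, m$K)) {
      if (max(abs(th[a, ] - th[b, ])) <= theta_sep) return(FALSE)
    }
    TRUE
  }, TRUE)
  base_gain <- if (length(ll) >= 2L && ks[1L] == 1L) ll[2L] - ll[1L] else
    max(diff(ll), 0)
  eligible <- !is.na(gain) & gain > gain_threshold * max(base_gain, 0) &
    distinct
  recommended <- if (any(eligible)) max(ks[eligible]) else k_min
  structure(list(
    table = data.frame(K = ks, loglik = ll, bic = bic, gain = gain,
                       distinct_profiles = distinct, eligible = eligible,
                       row.names = NULL),
    recommended_K = recommended,
    models = models), class = "KScanReport")
}

#' @method print KScanReport
#' @export
print.KScanReport <- function(x, ...) {
  print(x$table)
  cat("recommended K:", x$recommended_K, "\n")
  invisible(x)
}

#' Mean allele-frequency profile of each assigned clone
#'
#' Entry (k, v) is the pooled VAF `sum(AD) / sum(DP)` over the cells
#' labelled clone k; cells with zero coverage at a variant contribute
#' nothing. Clones with no covered cell at a variant get `NA` (missing,
#' not zero). This table is the export behind clone allele-frequency
#' heatmaps.
#'
#' @param model A fitted `CloneModel`.
#' @param acm The matrix the model was fitted on (or a compatible one).
#' @return A clone x variant numeric matrix.
#' @export
clone_variant_summary <- function(model, acm) {
  labels <- model$labels[acm$cell_ids]
  clones <- paste0("clone", seq_len(model$K) - 1L)
  AD <- as.matrix(acm$AD); DP <- as.matrix(acm$DP)
  out <- matrix(NA_real_, length(clones), ncol(AD),
                dimnames = list(clones, acm$variant_ids))
  for (k in clones) {
    mem <- which(labels == k)
    if (length(mem) == 0L) next
    num <- colSums(AD[mem, , drop = FALSE])
    den <- colSums(DP[mem, , drop = FALSE])
    out[k, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}
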