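# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their own seed from the master seed so that
#' stages can be re-run independently without perturbing one another.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param offset Integer offset identifying the stage or iteration.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 69069 + 12345 + abs(offset) * 1013904223) %% 2147483646)
}

# Evaluate an expression under a local RNG seed, restoring the caller's
# RNG state afterwards. NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Numerically stable log(sum(exp(x))) along matrix rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
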