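# Cell-by-variant allele-count container and variant identifiers.

#' Construct a cell-by-variant allele-count matrix
#'
#' Holds the alternate-allele depth (AD) and total depth (DP) for every
#' cell and mitochondrial variant. This pair of sparse integer matrices is
#' the substrate of all clonal inference: the per-cell variant allele
#' frequency (heteroplasmy) at a site is `AD / DP`.
#'
#' @param AD cell x variant matrix of alternate-allele read depths
#'   (coercible to a sparse `dgCMatrix`).
#' @param DP cell x variant matrix of total read depths, same shape.
#' @param cell_ids Character vector of unique cell barcodes (rows).
#' @param variant_ids Character vector of unique variant identifiers in
#'   `"<position><ref>><alt>"` form, e.g. `"7402C>T"` (columns).
#' @return An object of class `AlleleCountMatrix` with elements `AD`,
#'   `DP`, `cell_ids`, `variant_ids`.
#' @examples
#' acm <- allele_count_matrix(matrix(0:3, 2), matrix(4, 2, 2),
#'                            c("c1", "c2"), c("1G>A", "2C>T"))
#' dim(acm)
#' @export
allele_count_matrix <- function(AD, DP, cell_ids, variant_ids) {
  AD <- methods::as(methods::as(Matrix::Matrix(AD, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  DP <- methods::as(methods::as(Matrix::Matrix(DP, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  cell_ids <- as.character(cell_ids)
  variant_ids <- as.character(variant_ids)
  if (nrow(AD) != length(cell_ids) || ncol(AD) != length(variant_ids))
    stop("AD dimensions (", nrow(AD), " x ", ncol(AD),
         ") do not match ", length(cell_ids), " cells x ",
         length(variant_ids), " variants")
  if (!identical(dim(AD), dim(DP)))
    stop("AD and DP dimensions differ")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", cell_ids[duplicated(cell_ids)][1L])
  if (anyDuplicated(variant_ids))
    stop("duplicate variant ids: ", variant_ids[duplicated(variant_ids)][1L])
  if (any(AD@x < 0) || any(DP@x < 0))
    stop("negative counts are not allowed")
  bad <- AD - DP
  if (any(bad@x > 0)) {
    idx <- Matrix::which(bad > 0, arr.ind = TRUE)[1L, ]
    stop("AD exceeds DP at cell '", cell_ids[idx[1L]], "', variant '",
         variant_ids[idx[2L]], "'")
  }
  # keep ids on the matrices too so subsetting stays coherent
  dimnames(AD) <- dimnames(DP) <- list(cell_ids, variant_ids)
  structure(list(AD = AD, DP = DP,
                 cell_ids = cell_ids, variant_ids = variant_ids),
            class = "AlleleCountMatrix")
}

#' @export
dim.AlleleCountMatrix <- function(x) dim(x$AD)

#' @method print AlleleCountMatrix
#' @export
print.AlleleCountMatrix <- function(x, ...) {
  cat("AlleleCountMatrix:", nrow(x$AD), "cells x", ncol(x$AD), "variants\n")
  cat("  nonzero AD entries:", length(x$AD@x), "\n")
  cat("  median per-cell total depth:",
      stats::median(Matrix::rowSums(x$DP)), "\n")
  invisible(x)
}

#' Subset an allele-count matrix by cells and/or variants
#'
#' @param x An `AlleleCountMatrix`.
#' @param i Cell index (integer, logical or cell-id character vector).
#' @param j Variant index, same conventions.
#' @param ... ignored.
#' @return A new `AlleleCountMatrix`.
#' @export
`[.AlleleCountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$variant_ids)
  if (is.character(i)) i <- match(i, x$cell_ids)
  if (is.character(j)) j <- match(j, x$variant_ids)
  if (anyNA(i) || anyNA(j)) stop("unknown cell or variant id in subset")
  allele_count_matrix(x$AD[i, j, drop = FALSE], x$DP[i, j, drop = FALSE],
                      x$cell_ids[i], x$variant_ids[j])
}

#' Per-cell variant allele frequencies
#'
#' @param acm An `AlleleCountMatrix`.
#' @return A dense cell x variant matrix of `AD/DP`; entries with `DP == 0`
#'   are `NA` (no information, not zero heteroplasmy).
#' @export
vaf_matrix <- function(acm) {
  v <- as.matrix(acm$AD) / as.matrix(acm$DP)
  v[as.matrix(acm$DP) == 0] <- NA_real_
  v
}

#' Parse a mitochondrial variant identifier
#'
#' Variants are named by 1-based mitochondrial position, reference base
#' and alternate base, e.g. `"7402C>T"`.
#'
#' @param s Character vector of identifiers.
#' @return A data.frame with columns `position` (integer), `ref`, `alt`
#'   and the normalized `id`.
#' @examples
#' parse_variant_id("7402C>T")
#' @export
parse_variant_id <- function(s) {
  s <- as.character(s)
  m <- regmatches(s, regexec("^([0-9]+)([ACGT])>([ACGT])$", s))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed variant id: '", s[bad][1L],
         "' (expected \"<position><ref>><alt>\", e.g. \"7402C>T\")")
  position <- as.integer(vapply(m, `[`, "", 2L))
  ref <- vapply(m, `[`, "", 3L)
  alt <- vapply(m, `[`, "", 4L)
  if (any(position < 1L))
    stop("variant position must be >= 1 in '", s[position < 1L][1L], "'")
  same <- ref == alt
  if (any(same))
    stop("reference and alternate base are identical in '", s[same][1L], "'")
  data.frame(position = position, ref = ref, alt = alt,
             id = sprintf("%d%s>%s", position, ref, alt),
             stringsAsFactors = FALSE)
}

#' Format variant identifiers from parts
#' @param position Integer vector of 1-based positions.
#' @param ref,alt Single-base character vectors.
#' @return Character vector of `"<position><ref>><alt>"` ids.
#' @export
format_variant_id <- function(position, ref, alt) {
  ids <- sprintf("%d%s>%s", as.integer(position), ref, alt)
  parse_variant_id(ids)  # validates
  ids
}
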