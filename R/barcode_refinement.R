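# Detecting synthetic-barcode homoplasy with mitochondrial clones.
#
# Independent progenitors can receive the same lentiviral barcode from a
# finite pool, so a "barcode clone" may aggregate biologically unrelated
# cells. Mitochondrial clone labels provide an orthogonal clonal record:
# a barcode clone whose cells span several mitochondrial clones is a
# homoplasy artifact and is decomposed into refined (barcode, mito-clone)
# subclones.

#' Group cells into barcode clones by exact barcode identity
#'
#' @param barcodes A data.frame with columns `cell` and `barcode`. Cells
#'   with missing or empty barcodes are dropped and counted.
#' @return A list of class `BarcodeClones`: `clones` (named list of cell-id
#'   vectors, named by barcode), `n_dropped` (cells without a valid
#'   barcode).
#' @export
build_barcode_clones <- function(barcodes) {
  stopifnot(all(c("cell", "barcode") %in% names(barcodes)))
  bad <- is.na(barcodes$barcode) | !nzchar(trimws(barcodes$barcode))
  kept <- barcodes[!bad, , drop = FALSE]
  clones <- split(kept$cell, kept$barcode)
  structure(list(clones = clones, n_dropped = sum(bad)),
            class = "BarcodeClones")
}

#' Remove one-cell clones
#'
#' One-cell clones carry no information on shared ancestry and are dropped
#' before concordance analysis; their count and fraction of all clones are
#' reported.
#'
#' @param bc A `BarcodeClones` object (or a plain named list of clones).
#' @return A list: `clones` (multi-cell clones only), `singleton_count`,
#'   `singleton_fraction` (of all clones), `size_histogram` (table of
#'   retained clone sizes).
#' @export
filter_singletons <- function(bc) {
  clones <- if (inherits(bc, "BarcodeClones")) bc$clones else bc
  sizes <- vapply(clones, length, 1L)
  singletons <- sum(sizes == 1L)
  kept <- clones[sizes > 1L]
  list(clones = kept,
       singleton_count = singletons,
       singleton_fraction = if (length(clones)) singletons / length(clones)
                            else NaN,
       size_histogram = table(vapply(kept, length, 1L)))
}

#' Classify a clone as uni- or multi-lineage
#'
#' @param members Character vector of cell ids in the clone.
#' @param annotation Named character vector (or data.frame with `cell`,
#'   `lineage`) mapping cells to lineage labels.
#' @return `"uni"` if all members share one lineage, else `"multi"`.
#' @export
classify_lineage_breadth <- function(members, annotation) {
  ann <- as_annotation_vector(annotation)
  missing <- setdiff(members, names(ann))
  if (length(missing))
    stop("cell '", missing[1L], "' has no lineage annotation")
  if (length(unique(ann[members])) == 1L) "uni" else "multi"
}

as_annotation_vector <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("cell", "lineage") %in% names(annotation)))
    stats::setNames(as.character(annotation$lineage), annotation$cell)
  } else annotation
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("cell", "clone") %in% names(labels)))
    stats::setNames(as.character(labels$clone), labels$cell)
  } else labels
}

#' Mitochondrial concordance of barcode clones
#'
#' For every multi-lineage barcode clone, counts the distinct mitochondrial
#' clones among its assigned members. A clone is concordant when exactly
#' one mitochondrial clone is present (evidence for a genuine common
#' progenitor); a discordant clone merges several mitochondrial clones and
#' is flagged as a barcode-homoplasy artifact. Cells with an
#' `"unassigned"` or missing mitochondrial label are excluded from the
#' decision and counted.
#'
#' @param clones Named list of cell-id vectors (multi-cell barcode clones,
#'   e.g. from [filter_singletons()]).
#' @param mito_labels Named character vector (or data.frame `cell`,
#'   `clone`) of mitochondrial clone labels; `"unassigned"` is ignored.
#' @param annotation Lineage annotation as in
#'   [classify_lineage_breadth()].
#' @return A list of class `CloneConcordanceReport`: `per_clone`
#'   data.frame (`barcode`, `size`, `n_assigned`, `lineage_class`,
#'   `n_mito_clones`, `concordant`), aggregate counts
#'   (`n_multi_lineage_clones`, `n_concordant`, `n_discordant`),
#'   `clone_level_concordant_fraction`,
#'   `cell_level_concordant_fraction`, and `n_cells_unassigned`.
#' @export
concordance_report <- function(clones, mito_labels, annotation) {
  ml <- as_label_vector(mito_labels)
  per <- lapply(names(clones), function(bc) {
    members <- clones[[bc]]
    lab <- ml[members]
    assigned <- members[!is.na(lab) & lab != "unassigned"]
    mito <- unique(ml[assigned])
    data.frame(barcode = bc, size = length(members),
               n_assigned = length(assigned),
               lineage_class = classify_lineage_breadth(members, annotation),
               n_mito_clones = length(mito),
               concordant = length(mito) == 1L,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  multi <- per[per$lineage_class == "multi" & per$n_mito_clones >= 1L, ,
               drop = FALSE]
  n_multi <- nrow(multi)
  n_conc <- sum(multi$concordant)
  n_disc <- n_multi - n_conc
  cells_multi <- sum(multi$n_assigned)
  cells_conc <- sum(multi$n_assigned[multi$concordant])
  if (n_multi == 0L)
    warning("no multi-lineage clones: concordance fractions are missing")
  structure(list(
    per_clone = per,
    n_multi_lineage_clones = n_multi,
    n_concordant = n_conc,
    n_discordant = n_disc,
    clone_level_concordant_fraction =
      if (n_multi > 0L) n_conc / n_multi else NA_real_,
    cell_level_concordant_fraction =
      if (cells_multi > 0L) cells_conc / cells_multi else NA_real_,
    n_cells_unassigned = sum(per$size - per$n_assigned)),
    class = "CloneConcordanceReport")
}

#' @method print CloneConcordanceReport
#' @export
print.CloneConcordanceReport <- function(x, ...) {
  cat("CloneConcordanceReport:", nrow(x$per_clone), "multi-cell clones;",
      x$n_multi_lineage_clones, "multi-lineage\n")
  cat(sprintf("  concordant %d (%.1f%%), discordant %d (%.1f%%)\n",
              x$n_concordant, 100 * x$clone_level_concordant_fraction,
              x$n_discordant, 100 * (1 - x$clone_level_concordant_fraction)))
  invisible(x)
}

#' Refine barcode clones by mitochondrial clone membership
#'
#' Computes the common refinement (partition intersection) of the barcode
#' partition and the mitochondrial partition: each refined clone is the set
#' of cells sharing both one barcode and one mitochondrial clone. The
#' operation is idempotent and the result is finer than (or equal to) both
#' inputs.
#'
#' @inheritParams concordance_report
#' @return A data.frame with columns `refined_id` (`"<barcode>|<mito>"`),
#'   `barcode`, `mito_clone`, `cell`; cells lacking either label are
#'   omitted.
#' @export
refine_clones <- function(clones, mito_labels) {
  ml <- as_label_vector(mito_labels)
  out <- lapply(names(clones), function(bc) {
    members <- clones[[bc]]
    lab <- ml[members]
    keep <- !is.na(lab) & lab != "unassigned"
    if (!any(keep)) return(NULL)
    data.frame(refined_id = paste0(bc, "|", lab[keep]),
               barcode = bc, mito_clone = unname(lab[keep]),
               cell = members[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$refined_id, res$cell), , drop = FALSE]
}

#' Clone-by-lineage enrichment (Fisher exact + Benjamini-Hochberg)
#'
#' For every (clone, lineage) pair, tests the 2x2 table of membership
#' against lineage with a two-sided Fisher exact test, then adjusts all
#' p-values jointly by Benjamini-Hochberg.
#'
#' @inheritParams concordance_report
#' @return A data.frame `clone`, `lineage`, `in_clone_in_lineage`,
#'   `odds_ratio`, `p`, `q`.
#' @export
lineage_enrichment <- function(clones, annotation) {
  ann <- as_annotation_vector(annotation)
  all_cells <- unique(unlist(clones, use.names = FALSE))
  lineages <- sort(unique(ann[all_cells]))
  if (length(lineages) < 2L)
    stop("need at least 2 lineages for enrichment testing")
  rows <- list()
  for (bc in names(clones)) {
    members <- clones[[bc]]
    for (lin in lineages) {
      a <- sum(ann[members] == lin)
      b <- length(members) - a
      cc <- sum(ann[setdiff(all_cells, members)] == lin)
      d <- length(all_cells) - length(members) - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
      rows[[length(rows) + 1L]] <-
        data.frame(clone = bc, lineage = lin, in_clone_in_lineage = a,
                   odds_ratio = unname(ft$estimate), p = ft$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Lineage-pair frequencies of two-cell clones
#'
#' Unordered lineage pairs of all size-2 clones, same-lineage pairs
#' included, sorted by decreasing frequency; exposes fate-coupling biases
#' such as a mesenchymal-endothelial dominance among sister-cell pairs.
#'
#' @inheritParams concordance_report
#' @return A data.frame `pair` (e.g. `"EC+Mes-like"`, members sorted
#'   alphabetically), `count`, sorted descending.
#' @export
fate_coupling_counts <- function(clones, annotation) {
  ann <- as_annotation_vector(annotation)
  two <- clones[vapply(clones, length, 1L) == 2L]
  if (length(two) == 0L)
    return(data.frame(pair = character(), count = integer()))
  pairs <- vapply(two, function(members) {
    paste(sort(ann[members]), collapse = "+")
  }, "")
  tab <- sort(table(pairs), decreasing = TRUE)
  data.frame(pair = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
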