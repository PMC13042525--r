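# Readers and writers for the on-disk formats: MatrixMarket AD/DP pairs
# with VCF or TSV variant sidecars (the layout emitted by cellSNP-lite
# mode 2a), plain TSV tables, Visium-style spot-position CSVs, and the
# synthetic-truth JSON.

ad_names <- c("cellSNP.tag.AD.mtx", "AD.mtx")
dp_names <- c("cellSNP.tag.DP.mtx", "DP.mtx")
sample_names <- c("cellSNP.samples.tsv", "barcodes.tsv")

find_file <- function(dir, candidates, what) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("no ", what, " file found in '", dir, "' (looked for ",
       paste(candidates, collapse = ", "), ")")
}

#' Read an allele-count matrix directory
#'
#' Accepts the cellSNP-lite layout: `cellSNP.tag.AD.mtx` and
#' `cellSNP.tag.DP.mtx` MatrixMarket files (variant x cell), a
#' `cellSNP.samples.tsv` barcode sidecar, and either a sites-only
#' `cellSNP.base.vcf` or a `variants.tsv` sidecar naming the variants.
#' The two variant-sidecar dialects load to identical matrices.
#'
#' @param dir Directory containing the files.
#' @return An [allele_count_matrix()] (cells as rows); `AD <= DP` is
#'   enforced at load with the offending coordinate named on failure.
#' @export
read_allele_counts <- function(dir) {
  AD <- Matrix::readMM(find_file(dir, ad_names, "AD matrix"))
  DP <- Matrix::readMM(find_file(dir, dp_names, "DP matrix"))
  cells <- readLines(find_file(dir, sample_names, "cell barcode"))
  cells <- cells[nzchar(cells)]
  vcf_path <- file.path(dir, "cellSNP.base.vcf")
  tsv_path <- file.path(dir, "variants.tsv")
  if (file.exists(vcf_path)) {
    variants <- read_variant_vcf(vcf_path)
  } else if (file.exists(tsv_path)) {
    variants <- utils::read.delim(tsv_path, header = TRUE,
                                  stringsAsFactors = FALSE)$variant
    parse_variant_id(variants)
  } else {
    stop("no variant sidecar (cellSNP.base.vcf or variants.tsv) in '",
         dir, "'")
  }
  # cellSNP convention stores variants as rows; present cells as rows
  allele_count_matrix(Matrix::t(AD), Matrix::t(DP), cells, variants)
}

read_variant_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  format_variant_id(as.integer(fix[, "POS"]), fix[, "REF"], fix[, "ALT"])
}

#' Write an allele-count matrix directory
#'
#' Emits the cellSNP-lite layout read back by [read_allele_counts()]:
#' MatrixMarket AD/DP (variant x cell), the barcode sidecar, and both the
#' VCF and TSV variant sidecars.
#'
#' @param acm An [allele_count_matrix()].
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to overwrite existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_allele_counts <- function(acm, dir, overwrite = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cellSNP.tag.AD.mtx", "cellSNP.tag.DP.mtx",
                            "cellSNP.samples.tsv", "cellSNP.base.vcf",
                            "variants.tsv"))
  if (!overwrite && any(file.exists(paths)))
    stop("refusing to overwrite existing files in '", dir,
         "' (use overwrite = TRUE)")
  Matrix::writeMM(Matrix::t(acm$AD), paths[1L])
  Matrix::writeMM(Matrix::t(acm$DP), paths[2L])
  writeLines(acm$cell_ids, paths[3L])
  vp <- parse_variant_id(acm$variant_ids)
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrM,length=16569>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chrM\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       vp$position, vp$ref, vp$alt)), paths[4L])
  utils::write.table(data.frame(variant = acm$variant_ids), paths[5L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a delimited table with a required schema
#'
#' Delimiter (tab or comma) is sniffed from the header line; mandatory
#' columns missing from the file raise a schema error. Unknown columns are
#' preserved.
#'
#' @param path File path.
#' @param required Character vector of mandatory column names.
#' @return A data.frame.
#' @export
read_table_checked <- function(path, required = character()) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read a per-cell barcode table
#' @param path TSV/CSV with columns `cell`, `barcode`.
#' @return A data.frame.
#' @export
read_barcode_table <- function(path) {
  read_table_checked(path, c("cell", "barcode"))
}

#' Read a per-cell lineage annotation table
#'
#' @param path TSV/CSV with columns `cell`, `lineage`.
#' @param vocabulary Optional character vector of allowed lineage labels;
#'   labels outside it raise an error listing the offenders.
#' @return A data.frame.
#' @export
read_annotation_table <- function(path, vocabulary = NULL) {
  df <- read_table_checked(path, c("cell", "lineage"))
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(df$lineage), vocabulary)
    if (length(bad))
      stop("lineage label(s) outside the declared vocabulary: ",
           paste(bad, collapse = ", "))
  }
  df
}

visium_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row_in_fullres", "pxl_col_in_fullres")

#' Read a Visium-style spot position CSV
#'
#' Accepts both dialects: the headered `tissue_positions.csv` (columns
#' barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres) and the legacy headerless
#' `tissue_positions_list.csv` with the same six columns positionally.
#'
#' @param path CSV path.
#' @param replicate_id Identifier recorded for this section.
#' @return A `SpotGeometry` data.frame with the standard columns plus
#'   `replicate_id` and an empty `clone` column.
#' @export
read_visium_positions <- function(path, replicate_id = basename(dirname(path))) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) != 6L)
      stop("headerless positions file must have 6 columns, found ", ncol(df))
    names(df) <- visium_cols
  } else {
    miss <- setdiff(visium_cols, names(df))
    if (length(miss))
      stop("positions file missing column(s): ", paste(miss, collapse = ", "))
  }
  df$replicate_id <- replicate_id
  if (is.null(df$clone)) df$clone <- NA_character_
  class(df) <- c("SpotGeometry", "data.frame")
  df
}

#' Write spot positions in the headered Visium dialect
#' @param spots A `SpotGeometry` data.frame.
#' @param path Output CSV path.
#' @param overwrite Refuse to overwrite unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_visium_positions <- function(spots, path, overwrite = FALSE) {
  if (!overwrite && file.exists(path))
    stop("refusing to overwrite '", path, "' (use overwrite = TRUE)")
  utils::write.csv(as.data.frame(spots)[, visium_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Writes the allele-count directory, barcode and annotation TSVs, one
#' position CSV plus clone-label TSV per spatial replicate, and the
#' ground-truth JSON. Round-trips losslessly through the package readers.
#'
#' @param outdir Output directory.
#' @param acm,barcodes,annotation,spots,truth Outputs of the generator
#'   stages ([simulate_clonal_population()], [simulate_barcoding()],
#'   [simulate_spatial()]); any of the optional pieces may be `NULL`.
#' @param overwrite Refuse to overwrite existing output unless `TRUE`.
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(outdir, acm, barcodes = NULL, annotation = NULL,
                          spots = NULL, truth = NULL, overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("output directory '", outdir,
         "' is not empty (use overwrite = TRUE)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_allele_counts(acm, file.path(outdir, "matrix"), overwrite = overwrite)
  if (!is.null(barcodes))
    write_tsv(barcodes, file.path(outdir, "barcodes.tsv"))
  if (!is.null(annotation))
    write_tsv(annotation, file.path(outdir, "annotation.tsv"))
  if (!is.null(spots)) {
    if (inherits(spots, "data.frame")) spots <- list(spots)
    for (sg in spots) {
      rid <- sg$replicate_id[1L]
      rep_dir <- file.path(outdir, "spatial", rid)
      dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
      write_visium_positions(sg, file.path(rep_dir, "tissue_positions.csv"),
                             overwrite = overwrite)
      write_tsv(data.frame(barcode = sg$barcode, clone = sg$clone),
                file.path(rep_dir, "spot_clones.tsv"))
    }
  }
  if (!is.null(truth)) {
    tr <- truth
    class(tr) <- NULL
    tr$layout <- list(r_min = tr$layout[, 1L], r_max = tr$layout[, 2L])
    jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(outdir)
}
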