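# Pipeline orchestration: a single YAML-configurable entry point running
# filters -> delta-BIC variant selection -> K scan -> clone fit and the
# optional barcode-refinement, spatial and cluster-validation stages, each
# writing stable TSV/JSON outputs plus a machine-readable run manifest.

#' Build and validate a pipeline configuration
#'
#' @param x Either a path to a YAML file or a named list with the same
#'   structure: `counts_dir` (allele-count directory), optional
#'   `barcode_table`, `annotation_table`, `spatial_positions` (character
#'   vector of CSV paths), `outdir`, `seed`, and the parameter blocks
#'   `filters` (see [filter_config()]), `clones` (`k_min`, `k_max`,
#'   `restarts`, `min_prob`, ...) and `spatial` (`k_neighbors`,
#'   `n_perm`).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  if (is.null(cfg$counts_dir)) stop("config needs 'counts_dir'")
  if (!dir.exists(cfg$counts_dir))
    stop("counts_dir '", cfg$counts_dir, "' does not exist")
  for (p in c(cfg$barcode_table, cfg$annotation_table, cfg$spatial_positions))
    if (!file.exists(p)) stop("configured input '", p, "' does not exist")
  if (is.null(cfg$seed))
    stop("a seed is mandatory for the stochastic stages")
  cfg$outdir <- cfg$outdir %||% "mtclone_out"
  f <- cfg$filters %||% list()
  cfg$filters <- do.call(filter_config, f)
  cl <- cfg$clones %||% list()
  cfg$clones <- utils::modifyList(
    list(k_min = 1L, k_max = 6L, restarts = 3L, tol = 1e-6,
         max_iter = 300L, pseudocount = 0.2, min_prob = 0.8,
         gain_threshold = 0.02, theta_sep = 0.1), cl)
  sp <- cfg$spatial %||% list()
  cfg$spatial <- utils::modifyList(list(k_neighbors = 6L, n_perm = 999L), sp)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the clonal-inference pipeline
#'
#' Executes the configured stages in order, writing each stage's tables
#' under `cfg$outdir` together with `manifest.json` (parameters, seed,
#' input hashes) so that identical configs and inputs reproduce identical
#' outputs. Stage failures abort with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Which stages to run; stages whose inputs are not
#'   configured are skipped and noted in the manifest.
#' @param verbose Log progress to stderr.
#' @return A list bundle with the per-stage results (`scores`,
#'   `selection`, `kscan`, `model`, `concordance`, `spatial`,
#'   `validation`, `manifest`).
#' @export
run_pipeline <- function(cfg,
                         stages = c("filter", "select", "infer", "refine",
                                    "spatial", "validate"),
                         verbose = TRUE) {
  cfg <- if (inherits(cfg, "PipelineConfig")) cfg else pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list()
  manifest <- list(package = "mtclone",
                   version = as.character(utils::packageVersion("mtclone")),
                   seed = cfg$seed,
                   parameters = list(filters = unclass(cfg$filters),
                                     clones = cfg$clones,
                                     spatial = cfg$spatial),
                   inputs = input_hashes(cfg),
                   stages_run = character(), stages_skipped = character())
  run_stage <- function(name, fun) {
    msg("[mtclone] stage: ", name, verbose = verbose)
    tryCatch(fun(), error = function(e) {
      manifest$stages_run <<- c(manifest$stages_run, paste0(name, ":FAILED"))
      write_manifest(manifest, cfg$outdir)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  acm <- read_allele_counts(cfg$counts_dir)

  if ("filter" %in% stages) {
    acm <- run_stage("filter", function() {
      a <- apply_cell_filters(acm, cfg$filters)
      vf <- apply_variant_filters(a, cfg$filters)
      write_tsv(vf$excluded, file.path(cfg$outdir, "excluded_variants.tsv"))
      vf$acm
    })
    manifest$stages_run <- c(manifest$stages_run, "filter")
  }

  if ("select" %in% stages) {
    bundle$scores <- run_stage("select", function() {
      sc <- score_variants(acm, seed = derive_seed(cfg$seed, 101L))
      sc <- select_informative(sc)
      write_tsv(sc, file.path(cfg$outdir, "variant_scores.tsv"))
      ord <- attr(sc, "order")
      curve <- data.frame(rank = seq_along(ord), variant = ord,
                          cumulative_delta_bic =
                            cumsum(sc$delta_bic[match(ord, sc$variant)]))
      write_tsv(curve, file.path(cfg$outdir, "delta_bic_curve.tsv"))
      sc
    })
    manifest$stages_run <- c(manifest$stages_run, "select")
  }

  if ("infer" %in% stages) {
    res <- run_stage("infer", function() {
      sel <- bundle$scores$variant[bundle$scores$selected]
      if (length(sel) == 0L) stop("no informative variants selected")
      sub <- acm[, sel]
      ks <- scan_k(sub, k_min = cfg$clones$k_min, k_max = cfg$clones$k_max,
                   restarts = cfg$clones$restarts, tol = cfg$clones$tol,
                   max_iter = cfg$clones$max_iter,
                   pseudocount = cfg$clones$pseudocount,
                   min_prob = cfg$clones$min_prob,
                   gain_threshold = cfg$clones$gain_threshold,
                   theta_sep = cfg$clones$theta_sep,
                   seed = derive_seed(cfg$seed, 102L))
      model <- ks$models[[as.character(ks$recommended_K)]]
      write_tsv(ks$table, file.path(cfg$outdir, "k_scan.tsv"))
      write_tsv(data.frame(cell = names(model$labels),
                           clone = unname(model$labels),
                           max_prob = apply(model$gamma, 1L, max)),
                file.path(cfg$outdir, "clone_labels.tsv"))
      summ <- clone_variant_summary(model, sub)
      write_tsv(data.frame(clone = rownames(summ), summ,
                           check.names = FALSE),
                file.path(cfg$outdir, "clone_variant_summary.tsv"))
      list(kscan = ks, model = model)
    })
    bundle$kscan <- res$kscan
    bundle$model <- res$model
    manifest$stages_run <- c(manifest$stages_run, "infer")
  }

  if ("refine" %in% stages) {
    if (is.null(cfg$barcode_table) || is.null(cfg$annotation_table)) {
      manifest$stages_skipped <- c(manifest$stages_skipped,
                                   "refine (no barcode/annotation input)")
    } else {
      bundle$concordance <- run_stage("refine", function() {
        bc <- build_barcode_clones(read_barcode_table(cfg$barcode_table))
        fs <- filter_singletons(bc)
        ann <- read_annotation_table(cfg$annotation_table)
        rep <- concordance_report(fs$clones, bundle$model$labels, ann)
        refined <- refine_clones(fs$clones, bundle$model$labels)
        enr <- lineage_enrichment(fs$clones, ann)
        pairs <- fate_coupling_counts(fs$clones, ann)
        write_tsv(rep$per_clone, file.path(cfg$outdir, "concordance.tsv"))
        jsonlite::write_json(
          rep[setdiff(names(rep), "per_clone")],
          file.path(cfg$outdir, "concordance_summary.json"),
          auto_unbox = TRUE, digits = NA)
        write_tsv(refined, file.path(cfg$outdir, "refined_clones.tsv"))
        write_tsv(enr, file.path(cfg$outdir, "lineage_enrichment.tsv"))
        write_tsv(pairs, file.path(cfg$outdir, "fate_coupling.tsv"))
        rep
      })
      manifest$stages_run <- c(manifest$stages_run, "refine")
    }
  }

  if ("spatial" %in% stages) {
    if (is.null(cfg$spatial_positions)) {
      manifest$stages_skipped <- c(manifest$stages_skipped,
                                   "spatial (no position input)")
    } else {
      bundle$spatial <- run_stage("spatial", function() {
        spot_list <- lapply(cfg$spatial_positions, function(p) {
          sg <- read_visium_positions(p)
          lab_path <- file.path(dirname(p), "spot_clones.tsv")
          if (file.exists(lab_path)) {
            lab <- read_table_checked(lab_path, c("barcode", "clone"))
            sg <- attach_clone_labels(sg, lab)
          }
          sg
        })
        met <- spatial_metrics(spot_list,
                               k_neighbors = cfg$spatial$k_neighbors,
                               n_perm = cfg$spatial$n_perm,
                               seed = derive_seed(cfg$seed, 103L))
        write_tsv(met, file.path(cfg$outdir, "spatial_metrics.tsv"))
        cls <- met[, c("replicate_id", "clone", "position_class")]
        write_tsv(cls, file.path(cfg$outdir, "position_classes.tsv"))
        met
      })
      manifest$stages_run <- c(manifest$stages_run, "spatial")
    }
  }

  if ("validate" %in% stages && !is.null(bundle$model)) {
    bundle$validation <- run_stage("validate", function() {
      sel <- acm[, bundle$model$variant_ids]
      X <- vaf_matrix(sel)
      X[is.na(X)] <- 0
      lab <- bundle$model$labels
      keep <- lab != "unassigned"
      if (length(unique(lab[keep])) < 2L) return(NULL)
      hc <- stats::hclust(stats::dist(scale_vaf(X[keep, , drop = FALSE])),
                          method = "ward.D")
      alt <- stats::cutree(hc, k = bundle$model$K)
      tab <- compare_clusterings(X[keep, , drop = FALSE],
                                 list(mixture = lab[keep],
                                      hierarchical = paste0("h", alt)))
      write_tsv(tab, file.path(cfg$outdir, "cluster_validation.tsv"))
      tab
    })
    manifest$stages_run <- c(manifest$stages_run, "validate")
  }

  bundle$manifest <- manifest
  write_manifest(manifest, cfg$outdir)
  bundle
}

input_hashes <- function(cfg) {
  paths <- c(list.files(cfg$counts_dir, full.names = TRUE),
             cfg$barcode_table, cfg$annotation_table, cfg$spatial_positions)
  h <- tools::md5sum(paths)
  as.list(stats::setNames(unname(h), basename(paths)))
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}
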