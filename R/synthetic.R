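# Seeded generator for allele-count matrices, barcode tables, lineage
# annotations and spatial replicates with planted ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a small number of mitochondrial clones separated by heteroplasmic
# variants (bimodal VAF against a low sequencing-error background), a skewed
# progenitor (clone-size) distribution dominated by singletons, barcode
# collisions across independent progenitors, and disc-shaped spatial
# replicates in which clones occupy radial bands.

#' Configuration for the synthetic clonal-population generator
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: 500 cells in 3 mitochondrial clones, 10 informative variants among
#' 90 noise variants, mean per-site coverage 30, and 5 disc-shaped spatial
#' replicates with a peripheral, an intermediate and a central clone.
#'
#' @param n_cells Number of cells.
#' @param K Number of mitochondrial clones.
#' @param clone_proportions Simplex of length `K`; expected clone sizes.
#' @param n_informative Number of clone-informative variants (>= 1).
#' @param n_noise_variants Number of pure-noise variants.
#' @param mean_dp Mean per-cell, per-site total depth.
#' @param dp_dispersion Negative-binomial dispersion of the coverage law
#'   (variance `mu + dispersion * mu^2`); `0` gives Poisson coverage.
#' @param theta_high_range Range the carrier heteroplasmy of an informative
#'   variant is drawn from.
#' @param theta_error Background alternate-allele rate (sequencing error).
#' @param n_progenitors Reserved; `NULL` (the default) lets the number of
#'   progenitors emerge from `clone_size_law`.
#' @param barcode_pool_size Size of the synthetic-barcode pool progenitors
#'   draw from with replacement (smaller pools induce homoplasy).
#' @param clone_size_law List with elements `p` (zero-truncated-geometric
#'   success probability; equals the expected singleton fraction) and
#'   `max_size` (cap on cells per progenitor).
#' @param lineages Character vocabulary of lineage labels.
#' @param lineage_concentration Symmetric Dirichlet concentration of each
#'   progenitor's lineage-propensity vector; `0` makes every progenitor
#'   uni-lineage.
#' @param n_spatial_replicates,spots_per_replicate Spatial design.
#' @param disc_radius_px Disc radius in full-resolution pixels.
#' @param jitter_px Gaussian positional jitter (pixels).
#' @param layout `K x 2` matrix of radial bands `[r_min, r_max]` per clone,
#'   as fractions of the disc radius; `NULL` builds the default
#'   outside-in layout (clone 0 peripheral, last clone central).
#' @param seed Master integer seed; every stage derives its own sub-stream.
#' @return A validated list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_cells = 500L,
                             K = 3L,
                             clone_proportions = NULL,
                             n_informative = 10L,
                             n_noise_variants = 90L,
                             mean_dp = 30,
                             dp_dispersion = 0.3,
                             theta_high_range = c(0.3, 0.95),
                             theta_error = 0.002,
                             n_progenitors = NULL,
                             barcode_pool_size = 10000L,
                             clone_size_law = list(p = 0.65, max_size = 30L),
                             lineages = c("Mes-like", "EC", "Fibro", "PSC-Ect",
                                          "TB-like", "PSC-like", "Mes-PS",
                                          "endoderm"),
                             lineage_concentration = 1,
                             n_spatial_replicates = 5L,
                             spots_per_replicate = 300L,
                             disc_radius_px = 1000,
                             jitter_px = 10,
                             layout = NULL,
                             seed = 1L) {
  if (as.integer(K) < 1L) stop("K must be >= 1 (got ", K, ")")
  if (is.null(clone_proportions)) {
    # mildly skewed so clones are distinguishable but none is negligible
    w <- 0.75^(seq_len(K) - 1L)
    clone_proportions <- w / sum(w)
  }
  if (is.null(layout)) layout <- default_radial_layout(K)
  cfg <- structure(list(
    n_cells = as.integer(n_cells), K = as.integer(K),
    clone_proportions = as.numeric(clone_proportions),
    n_informative = as.integer(n_informative),
    n_noise_variants = as.integer(n_noise_variants),
    mean_dp = mean_dp, dp_dispersion = dp_dispersion,
    theta_high_range = theta_high_range, theta_error = theta_error,
    n_progenitors = n_progenitors,
    barcode_pool_size = as.numeric(barcode_pool_size),
    clone_size_law = clone_size_law,
    lineages = lineages, lineage_concentration = lineage_concentration,
    n_spatial_replicates = as.integer(n_spatial_replicates),
    spots_per_replicate = as.integer(spots_per_replicate),
    disc_radius_px = disc_radius_px, jitter_px = jitter_px,
    layout = layout, seed = as.integer(seed)), class = "GeneratorConfig")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$K < 1L) stop("K must be >= 1 (got ", cfg$K, ")")
  if (cfg$n_informative < 1L)
    stop("n_informative must be >= 1: without informative variants there is ",
         "no clonal signal to recover")
  if (cfg$n_cells < 1L || cfg$n_noise_variants < 0L)
    stop("all counts must be positive")
  if (length(cfg$clone_proportions) != cfg$K)
    stop("clone_proportions must have length K")
  if (abs(sum(cfg$clone_proportions) - 1) > 1e-9)
    stop("clone_proportions must sum to 1 (off by ",
         format(abs(sum(cfg$clone_proportions) - 1)), ")")
  if (any(cfg$clone_proportions <= 0)) stop("clone_proportions must be > 0")
  if (cfg$theta_error >= min(cfg$theta_high_range))
    stop("theta_error must be below min(theta_high_range)")
  if (cfg$barcode_pool_size < 1) stop("barcode_pool_size must be >= 1")
  lay <- cfg$layout
  if (!is.matrix(lay) || nrow(lay) != cfg$K || ncol(lay) != 2L)
    stop("layout must be a K x 2 matrix of radial bands")
  if (any(lay[, 1L] > lay[, 2L]))
    stop("impossible radial band: r_min > r_max for clone ",
         which(lay[, 1L] > lay[, 2L])[1L] - 1L)
  if (any(lay < 0) || any(lay > 1))
    stop("radial bands must lie within [0, 1]")
  invisible(cfg)
}

#' Default outside-in radial layout for K clones
#'
#' Clone 0 occupies the disc periphery and the last clone the core, with
#' slightly overlapping annular bands in between (the zonation pattern the
#' spatial module is designed to detect).
#'
#' @param K Number of clones.
#' @param overlap Band widening applied to each side, as a fraction of the
#'   disc radius.
#' @return A `K x 2` matrix of `[r_min, r_max]` bands.
#' @export
default_radial_layout <- function(K, overlap = 0.05) {
  breaks <- seq(1, 0, length.out = K + 1L)
  lay <- cbind(pmax(0, breaks[-1L] - overlap),
               pmin(1, breaks[-(K + 1L)] + overlap))
  rownames(lay) <- paste0("clone", seq_len(K) - 1L)
  colnames(lay) <- c("r_min", "r_max")
  lay
}

#' Simulate a clonal cell population with heteroplasmic variants
#'
#' Cells are assigned to `K` mitochondrial clones. Each informative variant
#' carries in a uniformly random nonempty proper subset of clones (resampled
#' until every clone pair is separable by at least one variant) at a
#' heteroplasmy drawn from `theta_high_range`; in non-carrier clones and for
#' all noise variants the alternate-allele rate is `theta_error`. Total
#' depth follows a negative-binomial coverage law and `AD ~ Binomial(DP,
#' theta)`.
#'
#' @param cfg A [generator_config()].
#' @return A list with `acm` (an [allele_count_matrix()]) and `truth`, the
#'   planted ground truth (clone of every cell, informative variant ids,
#'   per-variant carrier sets and heteroplasmies, layout, seed).
#' @examples
#' sim <- simulate_clonal_population(generator_config(n_cells = 50,
#'   n_informative = 2, n_noise_variants = 3, seed = 7))
#' table(sim$truth$clone_of_cell)
#' @export
simulate_clonal_population <- function(cfg) {
  validate_generator_config(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    K <- cfg$K
    n <- cfg$n_cells
    clone <- sample.int(K, n, replace = TRUE, prob = cfg$clone_proportions) - 1L
    # guarantee no empty clone so planted structure matches K
    for (k in seq_len(K) - 1L) {
      if (!any(clone == k)) clone[sample.int(n, 1L)] <- k
    }
    n_var <- cfg$n_informative + cfg$n_noise_variants
    pos <- sort(sample.int(16569L, n_var))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    vid <- format_variant_id(pos, ref, alt)
    informative <- vid[seq_len(cfg$n_informative)]

    carriers <- sample_separable_carriers(K, cfg$n_informative)
    theta_high <- stats::runif(cfg$n_informative,
                               cfg$theta_high_range[1L], cfg$theta_high_range[2L])

    # per-cell x variant success probability
    theta <- matrix(cfg$theta_error, n, n_var)
    for (v in seq_len(cfg$n_informative)) {
      in_carrier <- clone %in% carriers[[v]]
      theta[in_carrier, v] <- theta_high[v]
    }
    dp <- draw_depth(n * n_var, cfg$mean_dp, cfg$dp_dispersion)
    ad <- stats::rbinom(n * n_var, dp, as.vector(theta))
    cell_ids <- sprintf("c%05d", seq_len(n))
    acm <- allele_count_matrix(matrix(ad, n, n_var), matrix(dp, n, n_var),
                               cell_ids, vid)
    truth <- structure(list(
      clone_of_cell = stats::setNames(clone, cell_ids),
      informative_variants = informative,
      carrier_clones = stats::setNames(carriers, informative),
      theta_high = stats::setNames(theta_high, informative),
      theta_error = cfg$theta_error,
      progenitor_of_cell = NULL, barcode_of_progenitor = NULL,
      clone_of_progenitor = NULL, collision_groups = NULL,
      lineage_of_cell = NULL,
      layout = cfg$layout, seed = cfg$seed), class = "SyntheticTruth")
    list(acm = acm, truth = truth)
  })
}

draw_depth <- function(n, mean_dp, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mean_dp)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mean_dp)
}

# Uniform nonempty proper subsets of clones (0-based), resampled until every
# clone pair differs on at least one variant's carrier status. With K = 1
# there is no proper subset, so the single clone carries everything.
sample_separable_carriers <- function(K, n_informative, max_tries = 1000L) {
  if (K == 1L) return(replicate(n_informative, 0L, simplify = FALSE))
  if (n_informative < ceiling(log2(K)))
    stop("n_informative = ", n_informative, " cannot pairwise-separate K = ",
         K, " clones (need at least ceiling(log2(K)))")
  for (try in seq_len(max_tries)) {
    carriers <- lapply(seq_len(n_informative), function(v) {
      size <- sample.int(K - 1L, 1L)
      sort(sample.int(K, size) - 1L)
    })
    sep <- TRUE
    for (a in seq_len(K - 1L)) {
      for (b in seq((a + 1L), K)) {
        if (!any(vapply(carriers, function(cs)
          xor((a - 1L) %in% cs, (b - 1L) %in% cs), TRUE))) sep <- FALSE
      }
    }
    if (sep) return(carriers)
  }
  stop("could not sample a pairwise-separable carrier assignment")
}

#' Simulate synthetic barcoding with homoplasy
#'
#' Partitions each clone's cells into progenitors whose sizes follow a
#' zero-truncated geometric law (majority singletons), assigns every
#' progenitor a barcode drawn uniformly with replacement from a finite pool
#' (so distinct progenitors can collide on one barcode, the homoplasy
#' mechanism), and draws per-cell lineage labels from a per-progenitor
#' Dirichlet propensity.
#'
#' @param truth A `SyntheticTruth` from [simulate_clonal_population()].
#' @param cfg The same [generator_config()].
#' @return A list with `barcodes` (data.frame `cell`, `barcode`),
#'   `annotation` (data.frame `cell`, `lineage`) and the updated `truth`
#'   (progenitor map, barcode map, collision groups, lineages).
#' @export
simulate_barcoding <- function(truth, cfg) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (cfg$barcode_pool_size < 1) stop("barcode_pool_size must be >= 1")
  with_seed(derive_seed(cfg$seed, 2L), {
    cells <- names(truth$clone_of_cell)
    clone <- truth$clone_of_cell
    prog_of_cell <- character(length(cells))
    names(prog_of_cell) <- cells
    clone_of_prog <- integer(0)
    prog_counter <- 0L
    p_law <- cfg$clone_size_law$p
    max_size <- cfg$clone_size_law$max_size %||% 30L
    for (k in sort(unique(clone))) {
      members <- sample(cells[clone == k])
      while (length(members) > 0L) {
        size <- min(rztgeom(p_law, max_size), length(members))
        prog_counter <- prog_counter + 1L
        pid <- sprintf("p%05d", prog_counter)
        prog_of_cell[members[seq_len(size)]] <- pid
        clone_of_prog[pid] <- k
        members <- members[-seq_len(size)]
      }
    }
    progs <- names(clone_of_prog)
    idx <- sample.int(cfg$barcode_pool_size, length(progs), replace = TRUE)
    bc_of_prog <- stats::setNames(encode_barcode(idx), progs)
    groups <- split(progs, bc_of_prog)
    collision_groups <- unname(groups[vapply(groups, length, 1L) >= 2L])

    # per-progenitor lineage propensities
    L <- length(cfg$lineages)
    lineage_of_cell <- character(length(cells))
    names(lineage_of_cell) <- cells
    for (pid in progs) {
      members <- cells[prog_of_cell == pid]
      prop <- rdirichlet1(L, cfg$lineage_concentration)
      lineage_of_cell[members] <- sample(cfg$lineages, length(members),
                                         replace = TRUE, prob = prop)
    }
    truth$progenitor_of_cell <- prog_of_cell
    truth$barcode_of_progenitor <- bc_of_prog
    truth$clone_of_progenitor <- clone_of_prog
    truth$collision_groups <- collision_groups
    truth$lineage_of_cell <- lineage_of_cell
    list(barcodes = data.frame(cell = cells,
                               barcode = unname(bc_of_prog[prog_of_cell]),
                               stringsAsFactors = FALSE),
         annotation = data.frame(cell = cells,
                                 lineage = unname(lineage_of_cell),
                                 stringsAsFactors = FALSE),
         truth = truth)
  })
}

# zero-truncated geometric: P(X = 1) = p, capped at max_size
rztgeom <- function(p, max_size) {
  min(stats::rgeom(1L, p) + 1L, max_size)
}

# Deterministic pool-index -> DNA string so arbitrarily large pools never
# need materializing.
encode_barcode <- function(idx, width = 16L) {
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    i <- i - 1
    out <- character(width)
    for (j in seq_len(width)) {
      out[j] <- bases[(i %% 4) + 1]
      i <- i %/% 4
    }
    paste(out, collapse = "")
  }, "")
}

# One draw from a symmetric Dirichlet; concentration 0 degenerates to a
# point mass on a uniformly chosen category (uni-lineage progenitors).
rdirichlet1 <- function(L, concentration) {
  if (concentration <= 1e-8) {
    prop <- numeric(L)
    prop[sample.int(L, 1L)] <- 1
    return(prop)
  }
  g <- stats::rgamma(L, shape = concentration)
  if (sum(g) == 0) g[sample.int(L, 1L)] <- 1
  g / sum(g)
}

#' Simulate disc-shaped spatial replicates with clone zonation
#'
#' Per replicate, each spot's clone is drawn from the configured clone
#' proportions and the spot is placed uniformly within that clone's radial
#' band of a disc, with Gaussian positional jitter. Coordinates follow the
#' spot-position pixel convention of [read_visium_positions()] (y is the
#' full-resolution pixel row and increases downward).
#'
#' @param truth A `SyntheticTruth` (supplies the layout).
#' @param cfg The [generator_config()].
#' @return A list of per-replicate data.frames (class `SpotGeometry`) with
#'   columns `replicate_id`, `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pxl_row_in_fullres`, `pxl_col_in_fullres`, `clone`.
#' @export
simulate_spatial <- function(truth, cfg) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  lay <- truth$layout
  if (any(lay[, 1L] > lay[, 2L]))
    stop("impossible radial band: r_min > r_max")
  with_seed(derive_seed(cfg$seed, 3L), {
    R <- cfg$disc_radius_px
    centre <- c(x = 1.2 * R, y = 1.2 * R)
    lapply(seq_len(cfg$n_spatial_replicates), function(rep_i) {
      n <- cfg$spots_per_replicate
      clone <- sample.int(cfg$K, n, replace = TRUE,
                          prob = cfg$clone_proportions) - 1L
      rmin <- lay[clone + 1L, 1L]
      rmax <- lay[clone + 1L, 2L]
      # uniform over the annulus area
      r <- R * sqrt(stats::runif(n, rmin^2, rmax^2))
      ang <- stats::runif(n, 0, 2 * pi)
      x <- centre["x"] + r * cos(ang) + stats::rnorm(n, 0, cfg$jitter_px)
      y <- centre["y"] + r * sin(ang) + stats::rnorm(n, 0, cfg$jitter_px)
      sg <- data.frame(
        replicate_id = sprintf("rep%d", rep_i),
        barcode = sprintf("rep%d_s%04d", rep_i, seq_len(n)),
        in_tissue = 1L,
        array_row = rank(y, ties.method = "first"),
        array_col = rank(x, ties.method = "first"),
        pxl_row_in_fullres = unname(y),
        pxl_col_in_fullres = unname(x),
        clone = sprintf("clone%d", clone),
        stringsAsFactors = FALSE)
      class(sg) <- c("SpotGeometry", "data.frame")
      sg
    })
  })
}

#' Expected homoplasy-driven discordance under the generative law
#'
#' Closed-form expectation of the fraction of multi-lineage barcode clones
#' that contain more than one mitochondrial clone, in the uni-lineage
#' progenitor limit (`lineage_concentration = 0`, where every progenitor's
#' cells share one uniformly chosen lineage, so a barcode clone is
#' multi-lineage exactly when it merges progenitors of different lineages).
#' For a barcode shared by `m` progenitors drawn without replacement from
#' the realized per-clone progenitor counts, the probability all `m` share
#' one mitochondrial clone is a ratio of binomial coefficients, and the
#' probability the group is multi-lineage is `1 - L^(1-m)`; the number of
#' barcodes with multiplicity `m` has a known binomial expectation.
#'
#' @param progenitor_clone_counts Integer vector: progenitors per
#'   mitochondrial clone (realized or expected).
#' @param pool_size Barcode pool size.
#' @param n_lineages Size of the lineage vocabulary.
#' @return Expected discordant fraction among multi-lineage barcode clones.
#' @export
expected_discordant_fraction <- function(progenitor_clone_counts, pool_size,
                                         n_lineages) {
  Pk <- as.numeric(progenitor_clone_counts)
  P <- sum(Pk)
  B <- pool_size
  L <- n_lineages
  m_max <- min(P, 60)
  if (m_max < 2) return(NaN)
  m <- 2:m_max
  w <- B * stats::dbinom(m, P, 1 / B)       # E[# barcodes with m progenitors]
  conc <- vapply(m, function(mm)
    sum(exp(lchoose(Pk, mm) - lchoose(P, mm))), 0)  # all same mito clone
  multi_lin <- 1 - L^(1 - m)
  sum(w * (1 - conc) * multi_lin) / sum(w * multi_lin)
}
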