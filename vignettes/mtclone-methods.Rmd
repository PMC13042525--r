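---
title: "Methods: mitochondrial clonal inference, barcode refinement and spatial clonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial clonal inference, barcode refinement and spatial clonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtclone)
```

## Overview

`mtclone` reconstructs clonal structure in single-cell experiments from
mitochondrial DNA (mtDNA) heteroplasmy, cross-checks it against expressed
synthetic barcodes, and quantifies the spatial architecture of clones in
spot-based transcriptomics. The pipeline is:

1. **Filtering** — remove cells without a usable variant observation and
   variants that are quasi-germline, too rare, or too weak.
2. **Variant informativeness** — score every variant by the BIC difference
   between a one- and a two-component binomial fit of its per-cell
   variant allele frequencies (VAFs), and cut the informative set at the
   knee of the cumulative score curve.
3. **Clone inference** — fit a K-component binomial mixture over the
   informative variants, scanning K with an elbow rule.
4. **Barcode refinement** — compare mitochondrial clones with
   exact-match barcode clones, flag barcode homoplasy, and intersect the
   two partitions.
5. **Spatial clonality** — boundary/radial distances, Moran's I with a
   permutation null, and peripheral/central classification per replicate.
6. **Cluster validation** — Davies–Bouldin, Dunn, silhouette and
   connectivity on the VAF matrix, comparing alternative labelings.

Everything is driven by two sparse cell-by-variant matrices: `AD`
(alternate-allele depth) and `DP` (total depth). The per-cell
heteroplasmy of a variant is `VAF = AD / DP`; entries with `DP = 0` are
*missing*, never zero.

## Variant informativeness by ΔBIC

A clone-informative variant has a bimodal VAF distribution: a carrier
heteroplasmy in the clones that acquired the mutation, and a background
error rate everywhere else. For each variant with counts
$(a_c, d_c)$ over covered cells we fit

* a single binomial, with closed-form MLE
  $\hat\theta = \sum_c a_c / \sum_c d_c$ (1 free parameter), and
* a two-component binomial mixture
  $\pi\,\mathrm{Bin}(a_c; d_c, \theta_1) +
   (1-\pi)\,\mathrm{Bin}(a_c; d_c, \theta_2)$
  (3 free parameters), maximized by EM.

The score is $\Delta\mathrm{BIC} = \mathrm{BIC}_1 - \mathrm{BIC}_2
 = 2(\ell_2 - \ell_1) - 2\log n_{\mathrm{eff}}$, with
$n_{\mathrm{eff}}$ the number of covered cells. Larger values support
bimodality. Both fits share the clamped parameter space
$\theta \in [10^{-6}, 1-10^{-6}]$, and one EM restart always starts from
the collapsed single-binomial solution, so $\ell_2 \ge \ell_1$ holds by
construction (asserted in the tests at tolerance $10^{-6}$).

Variants are sorted by decreasing score (position-ascending tie break)
and accumulated; the knee of the cumulative curve is the index with the
maximum perpendicular distance to the chord joining its endpoints. The
selected set is the prefix up to the knee intersected with
$\{\Delta\mathrm{BIC} > 0\}$; a flat curve has no knee and falls back to
the positive-score set.

```{r select}
cfg <- generator_config(seed = 42L)        # 500 cells, 3 clones, 10 + 90 variants
sim <- simulate_clonal_population(cfg)
acm <- apply_cell_filters(sim$acm)
scores <- select_informative(score_variants(acm, seed = 1L))
table(selected = scores$selected,
      planted = scores$variant %in% sim$truth$informative_variants)
```

## Clone inference

Cells are assigned by a K-clone binomial mixture: clone $k$ is a vector
$\theta_{k\cdot}$ of allele frequencies over the selected variants, and
cell $c$ has responsibility
$\gamma_{ck} \propto \pi_k \prod_v \mathrm{Bin}(a_{cv}; d_{cv},
\theta_{kv})$, computed in the log domain as two sparse matrix products.
The M-step uses symmetric Beta pseudocounts ($a_0 = b_0 = 0.2$) to keep
frequencies off the 0/1 boundary; the EM therefore maximizes a penalized
objective whose trace is recorded alongside the raw log-likelihood.
Clones are re-ordered canonically (descending $\pi$, then lexicographic
$\theta$) so repeated runs give identical reports, and cells whose
maximum responsibility falls below `min_prob` (default 0.8) stay
`"unassigned"`.

`scan_k()` fits K over a range and recommends the largest K whose
log-likelihood gain exceeds 2% of the K=1→2 gain *and* whose clones all
have pairwise-distinct profiles (max-abs θ difference > 0.1). The
profile-distinctness condition is what stops the elbow rule from
over-splitting: beyond the true K, extra components duplicate an
existing profile.

```{r infer}
sel <- sim$acm[, scores$variant[scores$selected]]
scan <- scan_k(sel, seed = 1L)
scan$recommended_K
model <- scan$models[[as.character(scan$recommended_K)]]
table(inferred = model$labels,
      truth = paste0("clone", sim$truth$clone_of_cell))
```

## Barcode homoplasy and refinement

Expressed lentiviral barcodes group cells into clones by exact identity,
but a finite barcode pool means independent progenitors can draw the
same barcode (homoplasy), producing spurious multi-progenitor "clones".
Mitochondrial clones provide an orthogonal record: after dropping
one-cell clones, every *multi-lineage* barcode clone is classified
**concordant** (exactly one mitochondrial clone among its assigned
members — consistent with a genuine common progenitor) or **discordant**
(several mitochondrial clones — a homoplasy artifact). Discordant clones
are decomposed by the common refinement of the two partitions
(`refine_clones()`), which is idempotent and finer than both inputs.
Fisher-exact lineage enrichment (BH-adjusted) and two-cell-clone
fate-coupling counts complete the module.

The generator has a closed-form oracle for this process:
`expected_discordant_fraction()` enumerates barcode multiplicities under
the binomial pool-draw law and hypergeometric clone-composition
probabilities, exactly valid in the uni-lineage progenitor limit
(`lineage_concentration = 0`). The acceptance suite verifies the
simulated discordant fraction against this expectation to within
Monte-Carlo error.

## Spatial clonality

Per replicate, the tissue is the convex hull of in-tissue spots. Each
clone receives its spots' mean distance to the hull boundary and to the
centroid; the clone with the smallest mean boundary distance is
`"peripheral"`, the largest `"central"`. Clone aggregation is tested by
Moran's I on the clone indicator with symmetrized binary k-nearest-
neighbour weights (`k = 6`, matching hexagonal spot packing) and a
permutation null, $p = (1 + \#\{I^* \ge I\}) / (1 + n_{\mathrm{perm}})$.
Paired t-tests across replicates compare clones' distance profiles.

## Internal cluster validation

Four standard internal validity metrics over the (per-variant
standardized) VAF matrix — Davies–Bouldin, Dunn, mean silhouette
(singletons contribute 0), and connectivity with neighbour depth 10 —
let alternative labelings of the same cells be ranked;
`compare_clusterings()` ranks by ascending Davies–Bouldin. All four are
implemented directly (tested against brute-force oracles and
`cluster::silhouette`), avoiding any heavy clustering dependency.

## The synthetic benchmark

`generator_config()` defaults define the benchmark used across the test
and acceptance suites: 500 cells in K=3 clones (proportions
$\propto 0.75^k$), 10 informative variants with carrier sets resampled
until every clone pair is separable, carrier heteroplasmy uniform on
[0.3, 0.95] against an error rate of 0.002, 90 pure-noise variants,
negative-binomial coverage with mean 30 and dispersion 0.3, a
zero-truncated-geometric progenitor-size law with 65% singletons,
a barcode pool of 10,000, eight lineage labels, and five disc-shaped
spatial replicates with an outside-in radial clone layout. Barcode pool
indices are encoded to 16-mer DNA deterministically, so pools up to
$10^9$ never materialize. Every stage derives an independent sub-seed
from the master seed, so stages can be re-run in isolation.

Known limitations of the generator: reads are independent given the cell
(no doublets or index hopping), coverage is identical across variants,
clone spatial bands are annular by construction, and the lineage process
ignores differentiation hierarchy — properties the inference makes no
use of, chosen to keep every module's ground truth exact.

## Design decisions

* **EM rather than variational inference for clone assignment.** With a
  modest number of discrete clones, a seeded multi-restart EM with
  canonical clone ordering is deterministic, fast and auditable; the
  pseudocount M-step supplies the same boundary regularization a Beta
  prior would.
* **`n_progenitors` is reserved.** The number of progenitors emerges
  from the clone-size law rather than being fixed, which keeps the
  singleton fraction — the quantity the size law is parameterized by —
  interpretable.
* **Problem sizes.** Benchmarks run at hundreds of cells and ~100
  variants so the full suite, including 200-simulation oracle
  comparisons and 1000-replicate permutation calibration, completes in
  a couple of minutes on one CPU.

## Reproducibility

`run_pipeline()` writes every stage table plus `manifest.json`
(package version, seed, parameters, MD5 of every input), and identical
configs reproduce byte-identical outputs. The `exec/mtclone` script
exposes the same stages as subcommands over one YAML config.
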