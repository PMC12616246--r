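# phenoscaper

Condition-resolved single-cell analysis of highly multiplexed mass
cytometry screens of immune-cell / organoid co-cultures —
"phenoscaping" — plus a companion scRNA-seq stem-cell index.

## Science

Engineered gamma-delta T cells and patient-derived colorectal cancer
organoids (PDOs) reshape each other when co-cultured: the tumour cells
blunt T-cell signalling and effector phenotype, while the T cells drive
therapeutic apoptosis in the tumour cells. Measuring this reciprocal
immunomodulation across many donors, engineering states, organoid lines
and treatments requires barcoded, pooled mass cytometry and
condition-level statistics. This package implements that analysis
stack:

* **Combinatorial debarcoding** — k-of-n barcode schemes (9-choose-4 =
  126-plex) with rank-based assignment, separation thresholds and
  doublet rejection.
* **Preprocessing** — arcsinh transform (cofactor 5), per-batch mean
  centering, threshold gating, and state-aware tables that refuse
  double transformation.
* **Shift statistics** — signed earth mover's distance (exact 1-D
  Wasserstein-1 with a median-direction sign) per marker, summarised as
  the x-bar EMD (mean absolute EMD over analysis channels); therapeutic
  apoptosis and cell-state (apoptotic / S / G0 / other) metrics.
* **Signalling networks** — kNN density-resampled mutual information
  (kNN-DREMI) over all ordered PTM pairs (110 for an 11-marker panel)
  and delta-DREMI rewiring vectors against matched controls.
* **Condition embeddings** — deterministic PCA and a
  diffusion-potential embedding (alpha-decay kernel, adaptive
  bandwidth, -log transition potentials, classical MDS).
* **Stem index** — scRNA-seq QC with strict printed bounds,
  size-factor normalisation excluding highly expressed genes,
  bin-matched gene-program scoring, and a revCSC-minus-proCSC stem
  cell index.
* **Synthetic generators** — every estimator ships with a generator
  that plants known shifts, dependencies, barcode codes, doublets,
  state fractions and program gradients, so the whole stack is
  validated against ground truth without instrument data.

## Worked example

`make_demo()` writes a small screen — 2 donors x {unmod, stIL15} T
cells x {none, PDO1-3} x {+/- opsonising antibody}, with organoid
monoculture baselines, 1,000 cells per condition pooled with 5%
doublets and two batches — and `run_pipeline()` takes it end to end:

```r
library(phenoscaper)
demo <- make_demo("results/demo", seed = 1, cells_per_condition = 1000)
res <- run_pipeline(demo$config_path, "results/pipeline")
#> stage debarcode: 32550 cells, 126 codes
#>   assigned 31047 / 32550 cells
#> stage gate: 2 gates
#> stage shift: 24 conditions
#> stage dremi: panel of 6 PTMs
#> stage embed
#> run complete: 7 outputs
```

The planted effect — the antibody shrinks co-culture marker shifts
while raising therapeutic apoptosis — comes straight out of
`results/pipeline/summary.tsv` (seed 1, digits abbreviated):

| pair | x̄EMD co-culture | x̄EMD + antibody | ther. apoptosis co-culture | + antibody |
|---|---|---|---|---|
| D1_stIL15_PDO1 | 0.288 | 0.157 | 24.7 | 41.8 |
| D1_unmod_PDO2  | 0.200 | 0.093 | 25.5 | 38.1 |
| D2_stIL15_PDO3 | 0.193 | 0.128 | 26.6 | 39.4 |

Across all 12 matched pairs the antibody reduces x̄EMD in 12/12, and
every therapeutic-apoptosis estimate sits within 3 points of its
planted value.

The scRNA-seq side recovers a planted stem-program gradient:

```r
cfg <- scrna_sim_config(n_cells = 2000, seed = 1)
sim <- generate_scrna_counts(cfg)
qc  <- qc_filter(sim$counts, sim$metadata)
qc$report
#>          kept   removed_umi removed_genes  removed_mito removed_ratio
#>          1668             0             0             1           331
#> genes_removed
#>           209
lg  <- log_transform(normalize_counts(qc$counts))
idx <- stem_cell_index(score_gene_program(lg, cfg$proCSC_genes),
                       score_gene_program(lg, cfg$revCSC_genes))
# Spearman rho against the planted program mix: 0.990
```

## Reproduction

The numbered drivers under `analysis/` regenerate everything under
`results/` from scratch:

```sh
Rscript analysis/01_simulate.R     # demo screen + scRNA cohort
Rscript analysis/02_pipeline.R     # debarcode -> gate -> shift -> DREMI -> embed
Rscript analysis/03_stem_index.R   # QC, normalisation, stem index
Rscript analysis/04_summary.R      # headline tables
```

The acceptance harness recomputes the headline quantities against the
installed package and writes them as JSON (seed 1 shown; any seed
works and all randomness derives from it):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Selected values at seed 1: `dremi_pair_count` 110,
`barcode_code_count` 126, `monoculture_design_count` 42,
`emd_oracle_max_abs_err` 8.9e-16, `singlet_assignment_accuracy_pct`
100, `doublet_false_assignment_rate_pct` 0.65,
`dremi_y_permutation_bits` 0.028,
`dremi_resampling_invariance_rel_dev` 0.061, shift-recovery relative
errors 0.0076 / 0.0037 / 0.00017 for planted deltas 0.5 / 1 / 2,
`therapeutic_apoptosis_recovered_points` 24.4 (planted 25),
`stem_index_spearman_rho` 0.987, `antibody_rescue_replicates_pct` 100.

## Package layout

* `R/` — the package: cell tables and I/O, synthetic generators,
  debarcoding, shift statistics, DREMI, embeddings, scRNA stem index,
  the pipeline runner and demo builder.
* `tests/testthat/` — oracle, property and acceptance suites.
* `analysis/` — numbered drivers reproducing the worked example.
* `scripts/acceptance.R` — seeded acceptance harness.
* `vignettes/phenoscaping-methods.Rmd` — methods notes and modelling
  choices.
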