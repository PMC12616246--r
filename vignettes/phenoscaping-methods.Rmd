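---
title: "Phenoscaping methods: shift statistics, DREMI networks and condition embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenoscaping methods: shift statistics, DREMI networks and condition embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in
`phenoscaper` and the modelling choices behind its synthetic data
generators. The package targets condition-resolved analysis of highly
multiplexed mass cytometry screens of immune-cell / organoid
co-cultures, plus a companion scRNA-seq stem-cell index.

```{r setup}
library(phenoscaper)
```

## 1. Data model and preprocessing

A `cell_table` holds an events-by-channels intensity matrix, a channel
role map (`barcode`, `DNA`, `viability`, `lineage`, `state`, `PTM`,
`immunophenotype`, `other`) and per-cell metadata. Tables carry an
explicit transform state (`raw`, `arcsinh`, `centered`); operations that
require a particular state refuse to run otherwise, so a table can never
be arcsinh-transformed twice by accident.

* `arcsinh_transform()` applies `asinh(x / cofactor)` with the
  mass-cytometry convention `cofactor = 5`.
* `batch_mean_center()` subtracts per-batch, per-channel means on the
  transformed scale, removing additive batch offsets exactly.
* `gate_population()` applies threshold gates: a cell is positive for a
  channel when its value is strictly greater than the threshold, and
  negative when less than or equal to it. Gates are applied in order and
  do not overwrite earlier assignments.

## 2. Combinatorial debarcoding

Samples are multiplexed with a k-of-n barcode scheme (`9`-choose-`4`
gives the 126-plex layout). `debarcode()` is a single-pass rank
debarcoder:

1. each barcode channel is rescaled to [0, 1] over its 1st–99th
   percentile window (robust to outliers);
2. per cell, the candidate code is the set of the top `k_hot` rescaled
   channels;
3. the *separation* is the gap between the k-th and (k+1)-th ranked
   rescaled intensity; cells are assigned when the candidate code is a
   valid scheme code and the separation exceeds the threshold
   (default 0.3).

Doublets — channel-wise sums of two cells — light up more than `k_hot`
channels, so their separation collapses toward zero and they are
rejected. When a design uses fewer conditions than codes,
`enumerate_scheme()` maps conditions to codes spaced evenly across the
enumeration, so every barcode channel is represented in both hot and
cold states; this balance is what makes the per-channel percentile
rescaling well-posed on partial plates.

```{r debarcode-demo}
scheme <- enumerate_scheme(9, 4)
length(scheme$codes)
```

## 3. Signed EMD shift statistics

Marker-distribution shifts between a condition and its matched control
are scored with a signed earth mover's distance. The magnitude is the
exact 1-D Wasserstein-1 distance — the integral of the absolute CDF
difference on the pooled support, so unequal sample sizes are handled
without subsampling; for equal sizes it reduces to the mean absolute
difference of the sorted samples. The sign is the direction of the
median difference. Two useful exact properties:
`signed_emd(x + c, x) = c`, and symmetry
`signed_emd(y, x) = -signed_emd(x, y)`.

```{r emd}
signed_emd(c(1, 1, 2, 2), c(0, 0, 1, 1))
```

The per-condition summary is the x-bar EMD: the mean of absolute
per-marker EMDs over all non-barcode, non-DNA, non-viability channels —
a coordinate sliced Wasserstein distance that quantifies the overall
magnitude of phenotypic modulation.

Cell-state metrics use a priority hierarchy (`apoptotic` if
cPARP-positive, else `S` if IdU-positive, else `G0` if pRB-negative,
else `other`). `therapeutic_apoptosis()` is the apoptotic fraction of
the gated epithelial population in co-culture minus the matched organoid
monoculture baseline, in percentage points.

## 4. kNN-DREMI and delta-DREMI rewiring

`knn_dremi()` scores the strength of a response function y = f(x)
between two phospho-markers, insensitive to the cell-density
distribution along x:

1. rescale x and y to [0, 1], clipping 0.1/99.9 percentile tails;
2. estimate the joint density on a fine `(n_bins * n_mesh)^2` grid with
   the k-nearest-neighbour estimator `k / (N * pi * r_k^2)`;
3. aggregate to `n_bins x n_bins` coarse bins and renormalise each
   x-column into a conditional `p(y | x)`;
4. report the mutual information (bits) of the density-resampled joint.

Defaults are `k = 10`, `n_bins = 20`, `n_mesh = 3`; scores are bounded
by `log2(n_bins)` and are deterministic for fixed inputs. The estimator
uses a kd-tree (`RANN`) when available and an exact chunked brute-force
search otherwise — both give identical results.

A condition's signalling network is the DREMI score over all ordered
PTM pairs (`enumerate_pairs()`; an 11-marker panel has 110 pairs), and
rewiring relative to a control is the per-pair difference
(`delta_dremi()`).

## 5. Condition embeddings

Condition-level feature vectors (per-marker signed EMDs or per-pair
delta-DREMI values, assembled by `condition_matrix()`) are embedded
in 2-D two ways:

* `pca_embed()` — deterministic PCA with component signs fixed by
  making each component's largest-magnitude loading positive;
* `diffusion_potential_embed()` — an alpha-decay kernel
  `exp(-(d/sigma_i)^alpha)` with adaptive bandwidth (distance to the
  k-th nearest row), symmetrised and row-normalised to a Markov matrix,
  powered to `t` steps; potential coordinates are `-log` transition
  probabilities (floored at 1e-7), mapped to 2-D by classical MDS.
  Defaults `k = 5`, `alpha = 10`, `t = 10`. The procedure is fully
  deterministic; the seed argument is recorded in the settings for
  provenance only. This is a deliberate simplification of
  entropy-tuned diffusion embeddings: desk-scale condition counts need
  no landmarking or automatic diffusion-time selection, and the
  property we test is structure preservation (cluster separation, rank
  correlation of distances), not coordinate equality with any external
  tool.

## 6. scRNA-seq stem index

The scRNA-seq side follows printed bulk conventions, with all bounds
strict:

* `qc_filter()` removes cells with more than 32,500 or fewer than 1,000
  UMIs, more than 7,000 or fewer than 300 detected genes, more than 20%
  mitochondrial transcripts, or a UMI/read ratio above 0.4; genes
  detected in fewer than 25 kept cells are then dropped.
* `normalize_counts()` computes per-cell size factors excluding genes
  that individually exceed 5% of the cell's total, scaling to 10,000;
  `log_transform()` applies `ln(1 + x)` as a separate recorded step.
* `score_gene_program()` scores a program against expression-bin-matched
  control genes (25 bins, 50 controls per gene, seeded sampling).
* `stem_cell_index()` is the revCSC (revival) score minus the proCSC
  (proliferative) score per cell.

## 7. Synthetic generators and planted truth

Because the primary data are instrument-scale, every method ships with
a generator that plants known effects:

* channels are Gaussian on the arcsinh scale and inverted to raw
  intensities via `cofactor * sinh(max(z, 0))`, so planted location
  shifts (`shift_map`) are *exact* on the analysis scale;
* PTM dependencies of strength `s` are planted as
  `y = s * f(x) + (1 - s) * f(x_permuted) + noise`, which leaves the
  marginals of y invariant while scaling the DREMI signal;
* barcode channels use hot/cold means of 5.0/0.5 (sd 0.2) on the
  arcsinh scale — a well-separated design matching the premise of the
  debarcoder's validation suite;
* doublets are channel-wise raw-intensity sums of random cell pairs;
* cell states drive cPARP/IdU/pRB levels so planted apoptosis and
  S-phase fractions are recoverable by threshold gating.

`make_demo()` wires these into a small screen (2 donors x 2 engineering
states x 3 organoids, with and without an opsonising antibody) with a
planted effect in which the antibody shrinks co-culture marker shifts
while increasing therapeutic apoptosis — the direction the full
pipeline (`run_pipeline()`) recovers.

## Limitations

* The generators are deliberately simple (Gaussian channels, additive
  batch offsets, independent markers outside planted dependencies); they
  validate estimator correctness, not biological realism.
* The debarcoder assumes each barcode channel carries both hot and cold
  populations; fully degenerate designs (a channel hot in every pooled
  sample) are not supported and are avoided by the even-spread
  condition mapping.
* `knn_dremi()` scores are comparable only at fixed estimator settings;
  `delta_dremi()` enforces this.
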