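#!/usr/bin/env Rscript
# 01: lay down the synthetic demo screen (mass cytometry) and the
# synthetic scRNA-seq cohort. All downstream drivers read from results/.

suppressPackageStartupMessages(library(phenoscaper))

seed <- 1L
dir.create("results", showWarnings = FALSE)

# mass cytometry screen: 2 donors x {unmod, stIL15} x {none, PDO1-3}
# x {+/- mAb}, plus organoid monoculture baselines
demo <- make_demo("results/demo", seed = seed, cells_per_condition = 1000)
cat("demo written:", demo$config_path, "\n")

# scRNA-seq cohort with a planted proCSC/revCSC program gradient
scfg <- scrna_sim_config(n_cells = 2000, seed = seed)
ssim <- generate_scrna_counts(scfg)
write_gene_counts(ssim, "results/scrna")
mix_path <- "results/scrna/program_mix.tsv"
utils::write.table(
  data.frame(barcode = rownames(ssim$counts),
             program_mix = ssim$truth$program_mix),
  mix_path, sep = "\t", row.names = FALSE, quote = FALSE)
cat("scrna written: results/scrna (", nrow(ssim$counts), "cells )\n")
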