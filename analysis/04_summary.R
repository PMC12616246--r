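#!/usr/bin/env Rscript
# 04: collate the headline quantities of the run — antibody-rescue
# direction per matched co-culture pair, therapeutic apoptosis, and the
# largest delta-DREMI rewiring edges — into results/headline.tsv.

suppressPackageStartupMessages(library(phenoscaper))

summ <- utils::read.delim("results/pipeline/summary.tsv")
xb <- stats::setNames(summ$xbar_emd, summ$condition)
ta <- stats::setNames(summ$therapeutic_apoptosis, summ$condition)
coc <- grep("_PDO[0-9]+_r1$", summ$condition, value = TRUE)
mab <- sub("_r1$", "_mAb_r1", coc)

pairs <- data.frame(
  coculture = coc, antibody = mab,
  xbar_emd_coculture = unname(xb[coc]),
  xbar_emd_antibody = unname(xb[mab]),
  antibody_reduces_xbar_emd = unname(xb[mab] < xb[coc]),
  therapeutic_apoptosis_coculture = unname(ta[coc]),
  therapeutic_apoptosis_antibody = unname(ta[mab]))
utils::write.table(pairs, "results/headline.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(pairs, digits = 3)
cat(sprintf("antibody reduces xbar EMD in %d / %d matched pairs\n",
            sum(pairs$antibody_reduces_xbar_emd), nrow(pairs)))

dd <- utils::read.delim("results/pipeline/delta_dremi_wide.tsv",
                        check.names = FALSE)
long <- do.call(rbind, lapply(seq_len(nrow(dd)), function(i) {
  v <- unlist(dd[i, -1])
  data.frame(condition = dd$condition[i], pair = names(v),
             delta_dremi = unname(v))
}))
top <- long[order(-abs(long$delta_dremi)), ][1:10, ]
utils::write.table(top, "results/top_rewiring_edges.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("top rewiring edges:\n"); print(top, digits = 3, row.names = FALSE)
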