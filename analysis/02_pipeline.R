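#!/usr/bin/env Rscript
# 02: end-to-end condition screen on the demo data — debarcode, gate,
# per-condition signed-EMD shift profiles, DREMI / delta-DREMI, and the
# condition embeddings. Outputs land in results/pipeline/.

suppressPackageStartupMessages(library(phenoscaper))

res <- run_pipeline("results/demo/pipeline_config.yaml", "results/pipeline")
cat("outputs:\n")
for (p in unlist(res$outputs)) cat("  ", p, "\n")
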