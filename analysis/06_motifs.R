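#!/usr/bin/env Rscript
# Stage 6: hypergeometric motif enrichment in marker peaks and aggregated
# Tn5 insertion footprints; the central dip should recover the generative
# insertion-depletion factor (1 - 0.5).
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "motifs",
             outdir = outdir)
fp <- fread(file.path(outdir, "footprints.tsv"))
ctr <- fp[abs(rel) <= 10, .(center = mean(normalized)), by = .(motif, group)]
cat("normalized footprint depth at the motif center (flank = 1):\n")
print(ctr[order(motif, center)][, .(motif, group, center = round(center, 3))])
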