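#!/usr/bin/env Rscript
# Stage 5: binarized accessible sets and Jaccard similarity across cell
# types; mean intra-cell-type Jaccard contrasting shared stromal types with
# organ-restricted types.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "jaccard",
             outdir = outdir)
ity <- fread(file.path(outdir, "intra_type_jaccard.tsv"))
stromal <- c("endothelial", "fibroblast", "macrophage")
cat("mean intra-type Jaccard:\n")
cat(sprintf("  shared stromal types:   %.3f\n",
            mean(ity[cell_type %in% stromal, mean_jaccard])))
cat(sprintf("  organ-restricted types: %.3f\n",
            mean(ity[!cell_type %in% stromal, mean_jaccard])))
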