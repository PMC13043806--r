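#!/usr/bin/env Rscript
# Stage 3: 5-kb tile matrix, 4-round iterative TF-IDF/LSI embedding with
# depth-correlated dimension removal, doublet scoring, SNN-Louvain
# clustering; agreement with the generative (tissue, cell type) populations.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(),
             stages = c("tiles", "embed", "cluster"), outdir = outdir)
cl <- fread(file.path(outdir, "clusters.tsv"))
cells <- read_cells_tsv(file.path(outdir, "truth", "cells.tsv"))
info <- cells[match(cl$barcode, barcode)]
tab <- table(cl$cluster, paste(info$tissue, info$cell_type))
cat(sprintf("clusters: %d (generative populations: %d)\n", nrow(tab),
            ncol(tab)))
cat(sprintf("cluster purity vs (tissue, type): %.3f\n",
            sum(apply(tab, 1, max)) / sum(tab)))
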