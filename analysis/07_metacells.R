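#!/usr/bin/env Rscript
# Stage 7: kernel archetypal metacells (90 metacells, 10 waypoint
# eigenvectors, epsilon 1e-5, 10..50 iterations + 5 refinement) after
# rank-based doublet filtering; purity against the generative populations.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "metacells",
             outdir = outdir)
asg <- fread(file.path(outdir, "metacells.tsv"))
cells <- read_cells_tsv(file.path(outdir, "truth", "cells.tsv"))
info <- cells[match(asg$barcode, barcode)]
lab <- paste(info$tissue, info$cell_type)
pur <- sapply(split(lab, asg$metacell), function(x) max(table(x)) / length(x))
cat(sprintf("distinct metacell ids: %d\n", length(unique(asg$metacell))))
cat(sprintf("median metacell purity: %.3f; fraction >= 0.8: %.3f\n",
            median(pur), mean(pur >= 0.8)))
obj <- fread(file.path(outdir, "metacell_objective.tsv"))
cat(sprintf("objective: %.1f -> %.1f over %d recorded steps\n",
            obj$objective[1], tail(obj$objective, 1), nrow(obj)))
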