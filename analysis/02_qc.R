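#!/usr/bin/env Rscript
# Stage 2: per-barcode QC (fragment depth, TSS enrichment) and retention at
# the >=1000 fragments / TSS >= 4 rule; checked against the planted truth.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "qc", outdir = outdir)
qc <- fread(file.path(outdir, "qc_metrics.tsv"))
cells <- read_cells_tsv(file.path(outdir, "truth", "cells.tsv"))
m <- merge(qc, cells, by = "barcode")
cat(sprintf("retained %d / %d barcodes\n", sum(m$pass_filter), nrow(m)))
cat(sprintf("normal cells retained: %.1f%%\n",
            100 * mean(m[!is_lowq & !is_doublet, pass_filter])))
cat(sprintf("planted low-quality cells excluded: %.1f%%\n",
            100 * mean(!m[is_lowq == TRUE, pass_filter])))
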