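#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-organ scATAC dataset (9 tissues,
# 3 shared stromal cell types + one organ-restricted type per tissue,
# planted housekeeping / tissue / cell-type peaks, doublets, low-quality
# cells, motif footprints) and write fragments + ground truth.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "simulate",
             outdir = outdir)
cells <- read_cells_tsv(file.path(outdir, "truth", "cells.tsv"))
peaks <- read_peaks_bed(file.path(outdir, "truth", "peaks.bed"))
cat(sprintf("barcodes: %d (%d doublets, %d low-quality)\n", nrow(cells),
            sum(cells$is_doublet), sum(cells$is_lowq)))
print(peaks[, .N, by = class])
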