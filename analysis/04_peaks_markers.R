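#!/usr/bin/env Rscript
# Stage 4: capped peak matrix (ceiling 4), distance-weighted gene activity
# scores, and Wilcoxon marker detection (peaks: FDR<=0.1, log2FC>=0.5;
# genes: FDR<=0.01, log2FC>=1.25) against the planted marker truth.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(),
             stages = c("peaks", "genescores", "markers"), outdir = outdir)
mk <- fread(file.path(outdir, "markers_peaks.tsv"))
peaks <- read_peaks_bed(file.path(outdir, "truth", "peaks.bed"))
rec <- sapply(sort(unique(mk$group)), function(ty) {
  planted <- peaks[class == "celltype" & owner == ty, peak_id]
  if (!length(planted)) return(NA_real_)
  mean(planted %in% mk[group == ty & passes == TRUE, feature])
})
cat("per-type planted marker-peak recall:\n")
print(round(rec, 3))
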