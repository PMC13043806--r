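#!/usr/bin/env Rscript
# Stage 8: tissue composition of metacells, chromatin-module detection with
# hypergeometric tissue association, and the headline experiment — held-out
# tissue-of-origin prediction for shared stromal cells.
suppressPackageStartupMessages({library(chromtrace); library(data.table)})
outdir <- "results/pipeline"
run_pipeline(pipeline_config(), sim_config(), stages = "trace",
             outdir = outdir)
comp <- fread(file.path(outdir, "tissue_composition.tsv"))
frac <- as.matrix(comp[, -1])
cat(sprintf("metacells with a >=80%% dominant tissue: %d / %d\n",
            sum(apply(frac, 1, max) >= 0.8), nrow(frac)))
mods <- fread(file.path(outdir, "modules.tsv"))
cat(sprintf("module-tissue associations at fdr < 0.05: %d\n",
            sum(mods$associated)))
acc <- fread(file.path(outdir, "origin_accuracy.tsv"))
cat(sprintf("held-out stromal tissue-of-origin accuracy: %.3f (n = %d, unclassified %d)\n",
            acc$accuracy, acc$n_test, acc$n_unclassified))
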