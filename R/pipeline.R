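PIPELINE_STAGES <- c("simulate", "qc", "tiles", "embed", "cluster", "peaks",
                     "genescores", "markers", "jaccard", "motifs",
                     "metacells", "trace")

#' Run the analysis pipeline
#'
#' Executes a contiguous slice of the stage sequence
#' simulate, qc, tiles, embed, cluster, peaks, genescores, markers, jaccard,
#' motifs, metacells, trace — each stage reading its inputs from `outdir`,
#' writing versioned outputs there, and logging the thresholds it consumed
#' to `pipeline.log`. Re-running with the same configuration and seed
#' reproduces the outputs. A stage whose upstream artifact is missing stops
#' with an error naming the stage to run first.
#'
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] (used by the simulate stage).
#' @param stages `"all"` or a contiguous subset of the stage list.
#' @param outdir artifact directory.
#' @return invisibly, the outdir.
#' @export
run_pipeline <- function(config = pipeline_config(), sim = sim_config(),
                         stages = "all", outdir = "chromtrace_run") {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  idx <- match(stages, PIPELINE_STAGES)
  if (anyNA(idx)) stopf("unknown stage(s): %s",
                        paste(stages[is.na(idx)], collapse = ", "))
  if (!identical(idx, idx[1]:(idx[1] + length(idx) - 1L))) {
    stopf("stages must be a contiguous slice of: %s",
          paste(PIPELINE_STAGES, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  for (s in stages) {
    switch(s,
      simulate = stage_simulate(config, sim, outdir, st),
      qc = stage_qc(config, outdir, st),
      tiles = stage_tiles(config, sim, outdir, st),
      embed = stage_embed(config, outdir, st),
      cluster = stage_cluster(config, outdir, st),
      peaks = stage_peaks(config, outdir, st),
      genescores = stage_genescores(config, outdir, st),
      markers = stage_markers(config, outdir, st),
      jaccard = stage_jaccard(config, outdir, st),
      motifs = stage_motifs(config, outdir, st),
      metacells = stage_metacells(config, outdir, st),
      trace = stage_trace(config, outdir, st))
  }
  invisible(outdir)
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stopf("missing artifact '%s'; run stage '%s' first", path, produced_by)
  }
  path
}

get_fragments <- function(outdir, st) {
  st$fragments %||% {
    st$fragments <- read_fragments(
      need_artifact(file.path(outdir, "fragments.tsv.gz"), "simulate"))
    st$fragments
  }
}

get_truth <- function(outdir, st) {
  st$truth %||% {
    need_artifact(file.path(outdir, "truth", "peaks.bed"), "simulate")
    st$truth <- read_truth(file.path(outdir, "truth"))
    st$truth
  }
}

get_cells <- function(outdir, st) {
  st$cells %||% {
    st$cells <- read_cells_tsv(
      need_artifact(file.path(outdir, "truth", "cells.tsv"), "simulate"))
    st$cells
  }
}

get_retained <- function(outdir, st) {
  st$retained %||% {
    qc <- data.table::fread(
      need_artifact(file.path(outdir, "qc_metrics.tsv"), "qc"))
    st$retained <- qc[pass_filter == TRUE, barcode]
    st$retained
  }
}

get_tiles <- function(outdir, st) {
  st$tiles %||% {
    need_artifact(file.path(outdir, "tiles", "matrix.mtx"), "tiles")
    st$tiles <- read_matrix(file.path(outdir, "tiles"))
    st$tiles
  }
}

get_embedding <- function(outdir, st) {
  st$embedding %||% {
    dt <- data.table::fread(
      need_artifact(file.path(outdir, "embedding.tsv"), "embed"))
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt$barcode
    st$embedding <- m
    m
  }
}

get_peak_matrix <- function(outdir, st) {
  st$peak_matrix %||% {
    need_artifact(file.path(outdir, "peak_matrix", "matrix.mtx"), "peaks")
    st$peak_matrix <- read_matrix(file.path(outdir, "peak_matrix"))
    st$peak_matrix
  }
}

stage_simulate <- function(config, sim, outdir, st) {
  truth <- build_truth(sim)
  fr <- simulate_fragments(truth, sim)
  write_fragments(fr$fragments, file.path(outdir, "fragments.tsv.gz"))
  write_truth(truth, fr$cells, file.path(outdir, "truth"))
  st$fragments <- fr$fragments
  st$truth <- truth
  st$cells <- fr$cells
  log_stage("simulate", sim[c("seed", "n_cells_per_type", "signal_fraction",
                              "doublet_rate", "lowq_cell_rate",
                              "footprint_depletion")], outdir)
}

stage_qc <- function(config, outdir, st) {
  fr <- get_fragments(outdir, st)
  truth <- get_truth(outdir, st)
  qc <- qc_metrics(fr, truth$genes, config)
  data.table::fwrite(qc, file.path(outdir, "qc_metrics.tsv"), sep = "\t")
  st$retained <- qc[pass_filter == TRUE, barcode]
  log_stage("qc", config[c("qc.min_fragments", "qc.min_tss_enrichment")],
            outdir)
}

stage_tiles <- function(config, sim, outdir, st) {
  fr <- get_fragments(outdir, st)
  retained <- get_retained(outdir, st)
  tm <- make_tile_matrix(fr[barcode %in% retained], sim$genome,
                         tile_bp = config$tiles.size_bp, barcodes = retained)
  write_matrix(tm, file.path(outdir, "tiles"))
  st$tiles <- tm
  log_stage("tiles", config["tiles.size_bp"], outdir)
}

stage_embed <- function(config, outdir, st) {
  tm <- get_tiles(outdir, st)
  res <- iterative_lsi(tm, config)
  emb <- res$embedding
  dt <- data.table::data.table(barcode = rownames(emb))
  dt <- cbind(dt, data.table::as.data.table(emb))
  data.table::fwrite(dt, file.path(outdir, "embedding.tsv"), sep = "\t")
  st$embedding <- emb
  st$lsi <- res$model
  dbl <- doublet_enrichment(tm, res$model, k = config$qc.doublet_k,
                            seed = config$seed)
  data.table::fwrite(dbl, file.path(outdir, "doublet_scores.tsv"), sep = "\t")
  log_stage("embed", config[c("lsi.iterations", "lsi.n_variable_features",
                              "lsi.n_dims", "lsi.depth_cor_cutoff",
                              "lsi.formula", "qc.doublet_k")], outdir)
}

stage_cluster <- function(config, outdir, st) {
  emb <- get_embedding(outdir, st)
  cl <- snn_cluster(emb, k_param = config$cluster.k_param,
                    resolution = config$cluster.resolution,
                    max_clusters = config$cluster.max_clusters,
                    seed = config$seed)
  data.table::fwrite(data.table::data.table(barcode = names(cl), cluster = cl),
                     file.path(outdir, "clusters.tsv"), sep = "\t")
  st$clusters <- cl
  log_stage("cluster", config[c("cluster.k_param", "cluster.resolution",
                                "cluster.max_clusters")], outdir)
}

stage_peaks <- function(config, outdir, st) {
  fr <- get_fragments(outdir, st)
  truth <- get_truth(outdir, st)
  retained <- get_retained(outdir, st)
  peaks <- if (config$peaks.source == "truth") {
    truth$peaks
  } else {
    cells <- get_cells(outdir, st)
    grp <- stats::setNames(paste(cells$tissue, cells$cell_type, sep = "|"),
                           cells$barcode)
    genome <- infer_genome(fr)
    call_peaks_pseudobulk(fr[barcode %in% retained], genome, groups = grp,
                          width = config$peak.width_bp,
                          p_cutoff = config$peak.poisson_p)
  }
  pm <- make_peak_matrix(fr[barcode %in% retained], peaks,
                         ceiling = config$peak.ceiling, barcodes = retained)
  write_matrix(pm, file.path(outdir, "peak_matrix"))
  data.table::fwrite(peaks[, .(chrom, start, end, peak_id)],
                     file.path(outdir, "peaks_used.bed"), sep = "\t",
                     col.names = FALSE)
  st$peak_matrix <- pm
  log_stage("peaks", config[c("peaks.source", "peak.ceiling")], outdir)
}

infer_genome <- function(fragments) {
  g <- fragments[, .(len = max(end) + 10000L), by = chrom]
  stats::setNames(g$len, g$chrom)
}

stage_genescores <- function(config, outdir, st) {
  tm <- get_tiles(outdir, st)
  truth <- get_truth(outdir, st)
  gs <- gene_scores(tm, truth$genes, decay_bp = config$genescore.decay_bp,
                    max_dist_bp = config$genescore.max_dist_bp,
                    upstream_ext_bp = config$genescore.upstream_ext_bp)
  write_matrix(gs, file.path(outdir, "gene_scores"))
  st$gene_scores <- gs
  log_stage("genescores", config[c("genescore.decay_bp",
                                   "genescore.max_dist_bp",
                                   "genescore.upstream_ext_bp")], outdir)
}

stage_markers <- function(config, outdir, st) {
  cells <- get_cells(outdir, st)
  retained <- get_retained(outdir, st)
  labels <- stats::setNames(cells$cell_type, cells$barcode)
  pm <- get_peak_matrix(outdir, st)
  mk_p <- marker_features(pm, labels[rownames(pm$counts)],
                          fdr = config$markers_peaks.fdr,
                          log2fc = config$markers_peaks.log2fc,
                          pseudocount = config$markers.pseudocount)
  data.table::fwrite(mk_p, file.path(outdir, "markers_peaks.tsv"), sep = "\t")
  gs_dir <- file.path(outdir, "gene_scores", "matrix.mtx")
  need_artifact(gs_dir, "genescores")
  gs <- st$gene_scores %||% read_matrix(file.path(outdir, "gene_scores"))
  mk_g <- marker_features(gs, labels[rownames(gs$counts)],
                          fdr = config$markers_genes.fdr,
                          log2fc = config$markers_genes.log2fc,
                          pseudocount = config$markers.pseudocount)
  data.table::fwrite(mk_g, file.path(outdir, "markers_genes.tsv"), sep = "\t")
  st$markers_peaks <- mk_p
  log_stage("markers", config[c("markers_peaks.fdr", "markers_peaks.log2fc",
                                "markers_genes.fdr", "markers_genes.log2fc")],
            outdir)
}

stage_jaccard <- function(config, outdir, st) {
  cells <- get_cells(outdir, st)
  pm <- get_peak_matrix(outdir, st)
  bcs <- rownames(pm$counts)
  # doublet barcodes mix two populations and have no single truth label;
  # exclude them (and any residual low-quality cells) from set building
  singlets <- cells[is_doublet == FALSE & is_lowq == FALSE, barcode]
  bcs <- intersect(bcs, singlets)
  info <- cells[match(bcs, barcode)]
  sets <- lapply(split(bcs, info$cell_type), function(b)
    accessible_set(pm, b, config$jaccard.min_fraction))
  J <- jaccard_matrix(sets)
  data.table::fwrite(data.table::as.data.table(J, keep.rownames = "cell_type"),
                     file.path(outdir, "jaccard_celltypes.tsv"), sep = "\t")
  intra <- intra_type_similarity(pm, bcs, info$cell_type, info$tissue,
                                 min_fraction = config$jaccard.min_fraction,
                                 min_cells = config$jaccard.min_cells,
                                 seed = config$seed)
  data.table::fwrite(intra, file.path(outdir, "intra_type_jaccard.tsv"),
                     sep = "\t")
  log_stage("jaccard", config[c("jaccard.min_fraction", "jaccard.min_cells")],
            outdir)
}

stage_motifs <- function(config, outdir, st) {
  truth <- get_truth(outdir, st)
  fr <- get_fragments(outdir, st)
  cells <- get_cells(outdir, st)
  pm <- get_peak_matrix(outdir, st)
  mk <- st$markers_peaks %||% data.table::fread(
    need_artifact(file.path(outdir, "markers_peaks.tsv"), "markers"))
  motifs <- sort(unique(stats::na.omit(truth$peaks$motif)))
  if (!length(motifs)) {
    log_stage("motifs", list(note = "no planted motifs"), outdir)
    return(invisible())
  }
  all_peaks <- colnames(pm$counts)
  hits_all <- data.table::rbindlist(lapply(motifs, function(m) {
    pkm <- truth$peaks[!is.na(motif) & motif == m]
    data.table::data.table(motif = m, peak_id = pkm$peak_id,
                           offset = pkm$summit - pkm$start,
                           strand = pkm$motif_strand, score = NA_real_,
                           chrom = pkm$chrom, center = pkm$summit)
  }))
  enr <- data.table::rbindlist(lapply(sort(unique(mk$group)), function(g) {
    mp <- mk[group == g & passes == TRUE, feature]
    if (!length(mp)) return(NULL)
    e <- motif_enrichment(hits_all, mp, all_peaks, fdr = config$motif.fdr,
                          log2fc = config$motif.log2fc)
    if (nrow(e)) e[, group := g]
    e
  }), fill = TRUE)
  data.table::fwrite(enr, file.path(outdir, "motif_enrichment.tsv"), sep = "\t")
  grp <- stats::setNames(cells$cell_type, cells$barcode)
  fp <- data.table::rbindlist(lapply(motifs, function(m) {
    p <- footprint(fr[barcode %in% rownames(pm$counts)],
                   hits_all[motif == m], groups = grp)
    p[, motif := m]
    p
  }))
  data.table::fwrite(fp, file.path(outdir, "footprints.tsv"), sep = "\t")
  log_stage("motifs", config[c("motif.fdr", "motif.log2fc")], outdir)
}

stage_metacells <- function(config, outdir, st) {
  emb <- get_embedding(outdir, st)
  pm <- get_peak_matrix(outdir, st)
  if (config$metacells.doublet_filter_rate > 0) {
    dbl <- data.table::fread(
      need_artifact(file.path(outdir, "doublet_scores.tsv"), "embed"))
    n_rm <- round(config$metacells.doublet_filter_rate * nrow(dbl))
    if (n_rm > 0) {
      rm_bc <- dbl[order(-doublet_enrichment)][seq_len(n_rm), barcode]
      emb <- emb[!rownames(emb) %in% rm_bc, , drop = FALSE]
    }
  }
  kern <- build_kernel(emb, k = config$metacells.kernel_k)
  init <- init_waypoints(kern, emb, n_archetypes = config$metacells.n,
                         n_waypoint_eigs = config$metacells.n_waypoint_eigs)
  model <- fit_archetypes(kern, init,
                          epsilon = config$metacells.convergence_epsilon,
                          min_iter = config$metacells.min_iter,
                          max_iter = config$metacells.max_iter,
                          refine_iter = config$metacells.refine_iter)
  asg <- assign_metacells(model, pm)
  data.table::fwrite(asg$assignment, file.path(outdir, "metacells.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::data.table(iteration = seq_along(model$objective) - 1L,
                                            objective = model$objective),
                     file.path(outdir, "metacell_objective.tsv"), sep = "\t")
  st$metacells <- asg
  st$archetypes <- model
  log_stage("metacells", config[c("metacells.n", "metacells.n_waypoint_eigs",
                                  "metacells.convergence_epsilon",
                                  "metacells.min_iter", "metacells.max_iter")],
            outdir)
}

stage_trace <- function(config, outdir, st) {
  cells <- get_cells(outdir, st)
  pm <- get_peak_matrix(outdir, st)
  asg <- st$metacells %||% {
    a <- data.table::fread(need_artifact(file.path(outdir, "metacells.tsv"),
                                         "metacells"))
    list(assignment = a)
  }
  tis <- stats::setNames(cells$tissue, cells$barcode)
  comp <- tissue_composition(asg$assignment, tis,
                             n_metacells = config$metacells.n)
  data.table::fwrite(data.table::as.data.table(comp$fractions,
                                               keep.rownames = "metacell"),
                     file.path(outdir, "tissue_composition.tsv"), sep = "\t")
  # chromatin modules within each shared stromal cell type: metacells of
  # that type, accessible-set Jaccard, tree cut at the tissue count, and
  # hypergeometric tissue association
  types <- stats::setNames(cells$cell_type, cells$barcode)
  tcomp <- tissue_composition(asg$assignment, types,
                              n_metacells = config$metacells.n)
  stromal_types <- c("endothelial", "fibroblast", "macrophage")
  mod_tabs <- list()
  for (ty in intersect(stromal_types, unique(cells$cell_type))) {
    mc_ids <- names(tcomp$majority)[!is.na(tcomp$majority) &
                                      tcomp$majority == ty]
    mc_ids <- mc_ids[!is.na(comp$majority[mc_ids])]
    if (length(mc_ids) < 4L) next
    sets <- lapply(mc_ids, function(m)
      accessible_set(pm, asg$assignment[metacell == as.integer(m), barcode],
                     config$jaccard.min_fraction))
    names(sets) <- mc_ids
    J <- jaccard_matrix(sets)
    mods <- detect_modules(J, comp$majority[mc_ids])
    tab <- mods$associations
    tab[, cell_type := ty]
    mod_tabs[[ty]] <- tab
  }
  data.table::fwrite(data.table::rbindlist(mod_tabs),
                     file.path(outdir, "modules.tsv"), sep = "\t")
  # held-out stromal tissue-of-origin tracing
  stromal <- cells[is_doublet == FALSE & is_lowq == FALSE &
                     !grepl("parenchymal", cell_type) &
                     barcode %in% rownames(pm$counts), barcode]
  tr <- trace_tissue_of_origin(pm, tis, cells = stromal, seed = config$seed,
                               fdr = config$markers_peaks.fdr,
                               log2fc = config$markers_peaks.log2fc)
  data.table::fwrite(tr$prediction, file.path(outdir, "origin_predictions.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::data.table(
    n_test = length(tr$test), n_unclassified = tr$n_unclassified,
    accuracy = tr$accuracy), file.path(outdir, "origin_accuracy.tsv"),
    sep = "\t")
  log_stage("trace", list(accuracy = round(tr$accuracy, 4),
                          n_test = length(tr$test)), outdir)
}
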