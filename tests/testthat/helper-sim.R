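# Shared simulation fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small 3-tissue dataset: fast (~5 s), used by module-level tests.
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, tissues = c("liver", "lung", "kidney"),
                   n_cells_per_type = 25,
                   genome = c(chr1 = 4e6, chr2 = 4e6),
                   n_housekeeping_peaks = 50, n_tissue_peaks_per_tissue = 12,
                   n_celltype_peaks_per_type = 12,
                   frags_per_cell_meanlog = log(2000),
                   frags_per_cell_sdlog = 0.3)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_sim_config()
    ds <- simulate_dataset(cfg)
    .fixtures$small <- c(ds, list(config = cfg))
  }
  .fixtures$small
}

# Default-scale dataset with QC, tiles, iterative LSI and peak matrix:
# the study conditions (9 tissues, 3 shared stromal types). Built once.
default_run <- function() {
  if (is.null(.fixtures$default)) {
    cfg <- sim_config(seed = 202)
    pc <- pipeline_config(seed = 202)
    ds <- simulate_dataset(cfg)
    qc <- qc_metrics(ds$fragments, ds$truth$genes, pc)
    retained <- filter_cells(qc, pc)
    tiles <- make_tile_matrix(ds$fragments[barcode %in% retained],
                              cfg$genome, pc$tiles.size_bp,
                              barcodes = retained)
    lsi <- iterative_lsi(tiles, pc)
    pm <- make_peak_matrix(ds$fragments[barcode %in% retained],
                           ds$truth$peaks, pc$peak.ceiling,
                           barcodes = retained)
    dbl <- doublet_enrichment(tiles, lsi$model, k = pc$qc.doublet_k,
                              seed = pc$seed)
    .fixtures$default <- list(config = cfg, pipeline = pc, truth = ds$truth,
                              fragments = ds$fragments, cells = ds$cells,
                              qc = qc, retained = retained, tiles = tiles,
                              lsi = lsi, peak_matrix = pm, doublets = dbl)
  }
  .fixtures$default
}

# labels helpers
cell_info <- function(run, barcodes) run$cells[match(barcodes, barcode)]

# Metacell stage on the default run (doublet filter -> kernel -> archetypes),
# cached; used by both the module tests and the acceptance suite.
metacell_run <- function() {
  if (is.null(.fixtures$metacells)) {
    run <- default_run()
    pc <- run$pipeline
    dbl <- run$doublets
    n_rm <- round(pc$metacells.doublet_filter_rate * nrow(dbl))
    rm_bc <- dbl[order(-doublet_enrichment)][seq_len(n_rm), barcode]
    emb <- run$lsi$embedding
    emb <- emb[!rownames(emb) %in% rm_bc, , drop = FALSE]
    kern <- build_kernel(emb, k = pc$metacells.kernel_k)
    init <- init_waypoints(kern, emb, n_archetypes = pc$metacells.n,
                           n_waypoint_eigs = pc$metacells.n_waypoint_eigs)
    model <- fit_archetypes(kern, init,
                            epsilon = pc$metacells.convergence_epsilon,
                            min_iter = pc$metacells.min_iter,
                            max_iter = pc$metacells.max_iter)
    pmall <- run$peak_matrix
    pm <- feature_matrix(pmall$counts[rownames(emb), , drop = FALSE], "peak",
                         pmall$depth[rownames(emb)])
    asg <- assign_metacells(model, pm)
    .fixtures$metacells <- list(model = model, assignment = asg, emb = emb,
                                pm = pm, kernel = kern)
  }
  .fixtures$metacells
}
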