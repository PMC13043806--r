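#' Pipeline configuration
#'
#' Builds the configuration object that every stage of the pipeline reads its
#' thresholds from. Defaults are the analysis parameters used throughout the
#' package: QC retention at >= 1000 fragments and TSS enrichment >= 4, K = 10
#' doublet neighbors, 5-kb tiles, 4 LSI iterations with clustering
#' resolutions c(0.1, 0.2, 0.4), 65,000 variable features, 30 dimensions with
#' a depth-correlation cutoff of 0.75, SNN clustering with k.param = 30,
#' resolution = 1 and at most 60 clusters, marker gene cutoffs FDR <= 0.01 and
#' log2FC >= 1.25, marker peak cutoffs FDR <= 0.1 and log2FC >= 0.5 on a peak
#' matrix capped at 4, motif enrichment cutoffs FDR <= 0.1 and log2FC >= 0.1,
#' a +/- 3000 bp TSS annotation window, and 90 metacells initialized from 10
#' waypoint eigenvectors with convergence tolerance 1e-5 between 10 and 50
#' iterations (plus 5 refinement iterations).
#'
#' @param ... named overrides using dotted keys, e.g.
#'   `pipeline_config(qc.min_fragments = 500)`. Unknown keys are an error.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    qc.min_fragments = 1000,
    qc.min_tss_enrichment = 4,
    qc.doublet_k = 10L,
    qc.tss_window_bp = 2000L,
    qc.tss_center_bp = 50L,
    qc.tss_flank_bp = 100L,
    qc.tss_eps = 0.1,
    tiles.size_bp = 5000L,
    lsi.iterations = 4L,
    lsi.resolutions = c(0.1, 0.2, 0.4),
    lsi.n_variable_features = 65000L,
    lsi.n_dims = 30L,
    lsi.depth_cor_cutoff = 0.75,
    lsi.formula = "log_tfidf_v1",
    cluster.k_param = 30L,
    cluster.resolution = 1,
    cluster.max_clusters = 60L,
    markers_genes.fdr = 0.01,
    markers_genes.log2fc = 1.25,
    markers_peaks.fdr = 0.1,
    markers_peaks.log2fc = 0.5,
    markers.pseudocount = 0.1,
    peak.ceiling = 4L,
    peak.width_bp = 500L,
    peak.poisson_p = 1e-4,
    peaks.source = "truth",
    motif.fdr = 0.1,
    motif.log2fc = 0.1,
    annotate.tss_window_bp = 3000L,
    genescore.decay_bp = 5000L,
    genescore.max_dist_bp = 100000L,
    genescore.upstream_ext_bp = 5000L,
    impute.k = 15L,
    jaccard.min_fraction = 0.05,
    jaccard.min_cells = 20L,
    jaccard.source = "accessible",
    metacells.n = 90L,
    metacells.n_waypoint_eigs = 10L,
    metacells.convergence_epsilon = 1e-5,
    metacells.min_iter = 10L,
    metacells.max_iter = 50L,
    metacells.refine_iter = 5L,
    metacells.kernel_k = 15L,
    metacells.doublet_filter_rate = 0.05
  )
  over <- list(...)
  if (length(over) && is.null(names(over))) stopf("config overrides must be named")
  cfg <- apply_config_overrides(cfg, over)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

apply_config_overrides <- function(cfg, over) {
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  }
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

validate_pipeline_config <- function(cfg) {
  pos <- c("qc.min_fragments", "qc.min_tss_enrichment", "qc.doublet_k",
           "tiles.size_bp", "lsi.iterations", "lsi.n_variable_features",
           "lsi.n_dims", "lsi.depth_cor_cutoff", "cluster.k_param",
           "cluster.resolution", "cluster.max_clusters", "markers_genes.fdr",
           "markers_genes.log2fc", "markers_peaks.fdr", "markers_peaks.log2fc",
           "peak.ceiling", "motif.fdr", "motif.log2fc",
           "annotate.tss_window_bp", "metacells.n",
           "metacells.n_waypoint_eigs", "metacells.convergence_epsilon",
           "metacells.min_iter", "metacells.max_iter")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0)) {
      stopf("config key '%s' must be positive", k)
    }
  }
  if (length(cfg$lsi.resolutions) != cfg$lsi.iterations - 1L) {
    stopf("lsi.resolutions must have length lsi.iterations - 1 (%d), got %d",
          cfg$lsi.iterations - 1L, length(cfg$lsi.resolutions))
  }
  if (!cfg$peaks.source %in% c("truth", "called")) {
    stopf("peaks.source must be 'truth' or 'called'")
  }
  if (!cfg$jaccard.source %in% c("accessible", "markers")) {
    stopf("jaccard.source must be 'accessible' or 'markers'")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys use the same dotted names as [pipeline_config()]; nested YAML maps are
#' flattened (`qc: {min_fragments: 1000}` becomes `qc.min_fragments`). A
#' `sim:` block, if present, is passed to [sim_config()]. Unknown keys are
#' errors so threshold typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return list with elements `pipeline` (a `pipeline_config`) and `sim`
#'   (a `sim_config` or NULL).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_block <- raw$sim
  raw$sim <- NULL
  flat <- flatten_config(raw)
  pipe <- do.call(pipeline_config, flat)
  sim <- if (!is.null(sim_block)) do.call(sim_config, flatten_config(sim_block)) else NULL
  list(pipeline = pipe, sim = sim)
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (k in names(x)) {
    key <- if (is.null(prefix)) k else paste(prefix, k, sep = ".")
    v <- x[[k]]
    if (is.list(v) && !is.null(names(v)) && all(nzchar(names(v)))) {
      out <- c(out, flatten_config(v, key))
    } else {
      out[[key]] <- if (is.list(v)) unlist(v) else v
    }
  }
  out
}

# One-line "stage consumed these thresholds" log record, appended to
# <dir>/pipeline.log when dir is given, otherwise emitted as a message.
log_stage <- function(stage, params, dir = NULL) {
  kv <- paste(names(params), vapply(params, function(p)
    paste(format(p, digits = 10), collapse = ","), ""), sep = "=")
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste(kv, collapse = " "))
  if (!is.null(dir)) {
    cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE, sep = "")
  } else {
    message(line)
  }
  invisible(line)
}
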