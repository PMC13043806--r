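#' Insertion counts around transcription start sites
#'
#' Every fragment contributes two Tn5 insertion sites (start and end - 1).
#' Each insertion within `window_bp` of its nearest TSS is tallied at its
#' strand-oriented relative position (+x downstream of the TSS). Planted TSS
#' windows in the simulator never overlap, so nearest-TSS assignment is
#' unambiguous; on real data overlapping windows are resolved to the nearest
#' TSS.
#'
#' @param fragments fragment data.table (chrom, start, end, barcode, count).
#' @param tss_list data.table with chrom, tss, strand.
#' @param window_bp half-window (default 2000).
#' @param by_barcode if TRUE return per-barcode relative-position counts as a
#'   long data.table (barcode, rel, n); otherwise a pooled vector of length
#'   `2 * window_bp + 1` named by relative position.
#' @export
insertion_profile <- function(fragments, tss_list, window_bp = 2000L,
                              by_barcode = FALSE) {
  if (nrow(tss_list) == 0) stopf("tss_list is empty")
  rel <- tss_relative_insertions(fragments, tss_list, window_bp)
  if (by_barcode) {
    return(rel[, .(n = sum(w)), by = .(barcode, rel)][order(barcode, rel)])
  }
  prof <- stats::setNames(numeric(2L * window_bp + 1L),
                          as.character(seq(-window_bp, window_bp)))
  if (nrow(rel)) {
    agg <- rel[, .(n = sum(w)), by = rel]
    prof[as.character(agg$rel)] <- agg$n
  }
  prof
}

# Long table of (barcode, rel, w): strand-oriented insertion offsets within
# +/-window of the nearest TSS. Chromosomes are unrolled onto one axis; TSSs
# sit far enough from chromosome ends that cross-chromosome neighbors always
# exceed the window.
tss_relative_insertions <- function(fragments, tss_list, window_bp) {
  chroms <- unique(c(fragments$chrom, tss_list$chrom))
  span <- vapply(chroms, function(ch) {
    max(c(fragments[chrom == ch, end], tss_list[chrom == ch, tss], 0L))
  }, 0)
  offs <- stats::setNames(c(0, cumsum(span + 2 * window_bp + 10)), c(chroms, ""))
  gtss <- offs[tss_list$chrom] + tss_list$tss
  o <- order(gtss)
  gtss <- gtss[o]
  tstrand <- tss_list$strand[o]

  ins <- data.table::data.table(
    g = c(offs[fragments$chrom] + fragments$start,
          offs[fragments$chrom] + fragments$end - 1L),
    barcode = rep(fragments$barcode, 2L),
    w = rep(fragments$count, 2L))
  i0 <- findInterval(ins$g, gtss)
  lo <- pmax(i0, 1L)
  hi <- pmin(i0 + 1L, length(gtss))
  d_lo <- abs(ins$g - gtss[lo])
  d_hi <- abs(ins$g - gtss[hi])
  use_hi <- d_hi < d_lo | i0 == 0L
  idx <- ifelse(use_hi, hi, lo)
  rel <- ins$g - gtss[idx]
  keep <- abs(rel) <= window_bp
  out <- data.table::data.table(barcode = ins$barcode[keep],
                                rel = as.integer(rel[keep]),
                                w = ins$w[keep])
  flip <- tstrand[idx[keep]] == "-"
  out[flip, rel := -rel]
  out
}

#' TSS enrichment score of an insertion profile
#'
#' Mean insertion count over relative positions within +/-`center_bp` of the
#' TSS divided by the mean over the outermost `flank_bp` positions of each
#' flank, with the flank mean floored at `eps` so sparse profiles cannot
#' divide by zero. A flat profile scores ~1; promoter-enriched libraries
#' score well above the retention threshold of 4.
#'
#' @param profile pooled vector from [insertion_profile()] (length
#'   `2 * window_bp + 1`).
#' @param window_bp,center_bp,flank_bp,eps scoring constants (defaults
#'   2000 / 50 / 100 / 0.1).
#' @return non-negative scalar.
#' @export
tss_enrichment_score <- function(profile, window_bp = 2000L, center_bp = 50L,
                                 flank_bp = 100L, eps = 0.1) {
  if (length(profile) != 2L * window_bp + 1L) {
    stopf("profile length %d does not match window %d", length(profile), window_bp)
  }
  pos <- seq(-window_bp, window_bp)
  center <- mean(profile[abs(pos) <= center_bp])
  flank <- mean(profile[abs(pos) >= window_bp - flank_bp + 1L])
  center / max(flank, eps)
}

#' Per-barcode QC metrics
#'
#' Computes fragment depth and TSS enrichment for every barcode and applies
#' the retention rule: keep a cell iff it has at least `qc.min_fragments`
#' fragments and TSS enrichment at least `qc.min_tss_enrichment` (boundary
#' values retained).
#'
#' @param fragments fragment data.table.
#' @param tss_list data.table with chrom, tss, strand (e.g. the simulator's
#'   gene table).
#' @param config a [pipeline_config()].
#' @return data.table (barcode, n_fragments, tss_enrichment, pass_filter).
#' @export
qc_metrics <- function(fragments, tss_list, config = pipeline_config()) {
  depth <- fragments[, .(n_fragments = sum(count)), by = barcode]
  win <- as.integer(config$qc.tss_window_bp)
  cb <- as.integer(config$qc.tss_center_bp)
  fb <- as.integer(config$qc.tss_flank_bp)
  flank_lo <- win - fb + 1L
  rel <- tss_relative_insertions(fragments, tss_list, win)
  bands <- rel[, .(center = sum(w[abs(rel) <= cb]),
                   flank = sum(w[abs(rel) >= flank_lo])), by = barcode]
  out <- merge(depth, bands, by = "barcode", all.x = TRUE)
  out[is.na(center), c("center", "flank") := 0]
  n_center <- 2L * cb + 1L
  n_flank <- 2L * fb
  out[, tss_enrichment := (center / n_center) /
        pmax(flank / n_flank, config$qc.tss_eps)]
  out[, c("center", "flank") := NULL]
  out[, pass_filter := n_fragments >= config$qc.min_fragments &
        tss_enrichment >= config$qc.min_tss_enrichment]
  out[]
}

#' Apply the cell-retention filter
#'
#' @param metrics data.table from [qc_metrics()] (or any table with
#'   n_fragments and tss_enrichment columns).
#' @param config a [pipeline_config()].
#' @return character vector of retained barcodes.
#' @export
filter_cells <- function(metrics, config = pipeline_config()) {
  keep <- metrics$n_fragments >= config$qc.min_fragments &
    metrics$tss_enrichment >= config$qc.min_tss_enrichment
  metrics$barcode[keep]
}

#' KNN doublet enrichment score
#'
#' Synthesizes `n_synthetic` artificial doublets by summing the tile counts
#' of random distinct cell pairs, projects real and synthetic profiles into
#' a fitted LSI basis, and scores each real cell by the fraction of its `k`
#' nearest neighbors (among real + synthetic) that are synthetic, normalized
#' by the expected fraction under uniform mixing. Scores near 1 are
#' neighborhood-typical; doublet barcodes score higher because they sit
#' among the synthetic doublet cloud.
#'
#' @param matrix a tile [feature_matrix()] over all barcodes to score.
#' @param lsi a fitted `lsi_model` (see [svd_embed()]); the basis must have
#'   been fitted on real cells.
#' @param k neighbors (default 10).
#' @param n_synthetic number of synthetic doublets (default: number of
#'   cells).
#' @param seed RNG seed for pair sampling.
#' @return data.table (barcode, doublet_enrichment).
#' @export
doublet_enrichment <- function(matrix, lsi, k = 10L, n_synthetic = NULL,
                               seed = 1L) {
  counts <- matrix$counts
  n_real <- nrow(counts)
  n_synthetic <- as.integer(n_synthetic %||% n_real)
  if (n_synthetic == 0L) {
    return(data.table::data.table(barcode = rownames(counts),
                                  doublet_enrichment = 0))
  }
  if (k >= n_real + n_synthetic) stopf("k must be < n_real + n_synthetic")
  synth <- with_seed(seed, {
    i <- sample.int(n_real, n_synthetic, replace = TRUE)
    j <- sample.int(n_real - 1L, n_synthetic, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # distinct partner
    counts[i, , drop = FALSE] + counts[j, , drop = FALSE]
  })
  rownames(synth) <- sprintf("SYN%06d", seq_len(n_synthetic))
  emb_real <- project_lsi(lsi, counts)
  emb_syn <- project_lsi(lsi, synth)
  nn <- FNN::get.knnx(rbind(emb_real, emb_syn), emb_real, k = k + 1L)
  idx <- nn$nn.index[, -1L, drop = FALSE]  # drop self
  f <- rowMeans(idx > n_real)
  expected <- n_synthetic / (n_synthetic + n_real)
  data.table::data.table(barcode = rownames(counts),
                         doublet_enrichment = f / expected)
}
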