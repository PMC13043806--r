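#' Distance-weighted gene activity scores
#'
#' Scores gene activity from accessibility near the gene body: the body is
#' extended `upstream_ext_bp` on the promoter side of the TSS; every feature
#' whose midpoint lies inside the extended body gets weight 1, features
#' within `max_dist_bp` of its nearest edge get `exp(-d / decay_bp)`, and
#' anything farther gets 0. Per-cell scores are the weighted sum of feature
#' counts, normalized to 10k per cell and `ln(1+x)` so they are
#' depth-comparable across tissues.
#'
#' @param matrix a tile or peak [feature_matrix()] whose column labels encode
#'   `chrom:start-end` intervals.
#' @param genes data.table with gene, chrom, strand, start, end, tss.
#' @param decay_bp exponential decay constant (default 5000).
#' @param max_dist_bp horizon beyond which weights are 0 (default 100000).
#' @param upstream_ext_bp promoter-side body extension (default 5000).
#' @return a gene_score [feature_matrix()] (raw, not imputed).
#' @export
gene_scores <- function(matrix, genes, decay_bp = 5000, max_dist_bp = 100000,
                        upstream_ext_bp = 5000) {
  feats <- parse_interval(colnames(matrix$counts))
  ext_start <- ifelse(genes$strand == "+",
                      pmax(0, genes$start - upstream_ext_bp), genes$start)
  ext_end <- ifelse(genes$strand == "+",
                    genes$end, genes$end + upstream_ext_bp)
  trip_i <- vector("list", nrow(genes))
  trip_x <- vector("list", nrow(genes))
  empty <- character(0)
  by_chrom <- split(seq_len(nrow(feats)), feats$chrom)
  mp_sorted <- lapply(by_chrom, function(idx) {
    o <- order(feats$midpoint[idx])
    list(idx = idx[o], mp = feats$midpoint[idx][o])
  })
  for (g in seq_len(nrow(genes))) {
    ms <- mp_sorted[[genes$chrom[g]]]
    if (is.null(ms)) { empty <- c(empty, genes$gene[g]); next }
    lo <- ext_start[g] - max_dist_bp
    hi <- ext_end[g] + max_dist_bp
    a <- findInterval(lo - 0.5, ms$mp) + 1L
    b <- findInterval(hi + 0.5 - 1, ms$mp)
    if (b < a) { empty <- c(empty, genes$gene[g]); next }
    sel <- a:b
    mp <- ms$mp[sel]
    d <- pmax(0, pmax(ext_start[g] - mp, mp - (ext_end[g] - 1L)))
    w <- exp(-d / decay_bp)
    w[d > max_dist_bp] <- 0
    nz <- w > 0
    if (!any(nz)) { empty <- c(empty, genes$gene[g]); next }
    trip_i[[g]] <- ms$idx[sel][nz]
    trip_x[[g]] <- w[nz]
  }
  if (length(empty)) {
    message(sprintf("%d gene(s) with no features within %d bp: %s%s",
                    length(empty), max_dist_bp,
                    paste(utils::head(empty, 3), collapse = ", "),
                    if (length(empty) > 3) ", ..." else ""))
  }
  W <- Matrix::sparseMatrix(
    i = as.integer(unlist(trip_i)),
    j = rep(seq_len(nrow(genes)), vapply(trip_i, length, 0L)),
    x = as.numeric(unlist(trip_x)), dims = c(nrow(feats), nrow(genes)),
    dimnames = list(colnames(matrix$counts), genes$gene))
  raw <- matrix$counts %*% W
  rs <- Matrix::rowSums(raw)
  norm <- Matrix::Diagonal(x = ifelse(rs > 0, 1e4 / rs, 0)) %*% raw
  norm <- methods::as(methods::as(methods::as(norm, "dMatrix"),
                                  "generalMatrix"), "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- list(rownames(matrix$counts), genes$gene)
  out <- feature_matrix(norm, flavor = "gene_score", depth = matrix$depth)
  attr(out, "imputed") <- FALSE
  out
}

#' Neighbor-smoothing imputation of gene scores
#'
#' Replaces each cell's score vector by the mean over its `k` nearest
#' embedding neighbors (self included) — one application of a row-stochastic
#' KNN smoother. `k = 1` is the identity; constant columns are fixed points.
#'
#' @param scores a gene_score [feature_matrix()].
#' @param embedding cells x dims matrix, rows aligned with `scores`.
#' @param k neighborhood size including self (default 15; clamped with a
#'   warning when it exceeds the number of cells).
#' @return imputed gene_score [feature_matrix()].
#' @export
impute_scores <- function(scores, embedding, k = 15L) {
  stopifnot(nrow(scores$counts) == nrow(embedding))
  n <- nrow(embedding)
  if (k > n) {
    warnf("k = %d exceeds %d cells; clamping", k, n)
    k <- n
  }
  if (k <= 1L) return(scores)
  nn <- FNN::get.knn(embedding, k = k - 1L)$nn.index
  S <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                            j = c(seq_len(n), as.vector(nn)),
                            x = 1 / k, dims = c(n, n))
  sm <- S %*% scores$counts
  sm <- methods::as(sm, "CsparseMatrix")
  dimnames(sm) <- dimnames(scores$counts)
  out <- feature_matrix(sm, flavor = "gene_score", depth = scores$depth)
  attr(out, "imputed") <- TRUE
  out
}

#' Annotate peaks to genes by TSS proximity
#'
#' Assigns a peak to every gene whose TSS lies within
#' `[start - window_bp, end + window_bp)`. The reported distance is the
#' signed bp offset from the TSS to the nearest peak edge (0 when the TSS
#' falls inside the peak; positive when the peak starts downstream of the
#' TSS in genomic coordinates).
#'
#' @param peaks data.table with chrom, start, end, peak_id.
#' @param genes data.table with gene, chrom, tss.
#' @param window_bp assignment window (default 3000).
#' @return data.table (peak_id, gene, distance); peaks matching no gene are
#'   absent (unannotated).
#' @export
annotate_peaks_to_genes <- function(peaks, genes, window_bp = 3000L) {
  pk <- data.table::as.data.table(peaks)
  if (!"peak_id" %in% names(pk)) {
    pk[, peak_id := sprintf("%s:%d-%d", chrom, start, end)]
  }
  pk2 <- pk[, .(chrom, peak_id, pstart = start, pend = end,
                lo = start - as.integer(window_bp),
                hi = end + as.integer(window_bp) - 1L)]
  gn <- data.table::as.data.table(genes)[, .(chrom, gene, tss, tss2 = tss,
                                             tss_pos = tss)]
  hits <- pk2[gn, on = .(chrom, lo <= tss, hi >= tss2), nomatch = NULL,
              allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(data.table::data.table(peak_id = character(), gene = character(),
                                  distance = integer()))
  }
  hits[, distance := data.table::fifelse(
    tss_pos >= pstart & tss_pos < pend, 0L,
    data.table::fifelse(tss_pos < pstart, pstart - tss_pos,
                        -(tss_pos - (pend - 1L))))]
  hits[, .(peak_id, gene, distance)][order(peak_id, gene)]
}
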