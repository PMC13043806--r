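#' Tissue composition of metacells
#'
#' Fraction of each metacell's cells contributed by every tissue, with the
#' majority tissue (ties broken lexicographically) and purity (the maximum
#' fraction). Empty metacells get a zero row and are flagged.
#'
#' @param assignment data.table (barcode, metacell) from
#'   [assign_metacells()].
#' @param tissue_labels named vector barcode -> tissue.
#' @param n_metacells total metacell ids (default: max id seen).
#' @return list with `fractions` (metacell x tissue matrix, non-empty rows
#'   sum to 1), `majority` (named character), `purity` (named numeric),
#'   `empty` (integer ids).
#' @export
tissue_composition <- function(assignment, tissue_labels,
                               n_metacells = NULL) {
  tis <- tissue_labels[assignment$barcode]
  if (anyNA(tis)) stopf("every assigned cell needs a tissue label")
  n_metacells <- n_metacells %||% max(assignment$metacell)
  tab <- table(factor(assignment$metacell, levels = seq_len(n_metacells)),
               tis)
  F <- unclass(tab)
  sizes <- rowSums(F)
  empty <- which(sizes == 0)
  F <- F / pmax(sizes, 1)
  majority <- colnames(F)[apply(F, 1L, which.max)]
  majority[empty] <- NA_character_
  purity <- apply(F, 1L, max)
  purity[empty] <- NA_real_
  names(majority) <- rownames(F)
  names(purity) <- rownames(F)
  if (length(empty)) warnf("%d empty metacell(s)", length(empty))
  list(fractions = F, majority = majority, purity = purity,
       empty = as.integer(empty))
}

#' Pearson correlation between cell-type and metacell profiles
#'
#' Aggregates peak counts per cell type, depth-normalizes both cell-type and
#' metacell profiles to counts-per-10k and `ln(1+x)`, and correlates each
#' (cell type, metacell) pair over the peak universe. Zero-variance profiles
#' yield missing values rather than 0.
#'
#' @param peak_matrix a peak [feature_matrix()].
#' @param assignment data.table (barcode, metacell).
#' @param type_labels named vector barcode -> cell type.
#' @return data.table (cell_type, metacell, r).
#' @export
celltype_metacell_correlation <- function(peak_matrix, assignment,
                                          type_labels) {
  counts <- peak_matrix$counts[assignment$barcode, , drop = FALSE]
  norm_prof <- function(p) {
    rs <- rowSums(p)
    log1p(p / pmax(rs, 1) * 1e4)
  }
  tp <- norm_prof(rowsum_sparse(counts, type_labels[assignment$barcode]))
  mp <- norm_prof(rowsum_sparse(counts, assignment$metacell))
  out <- data.table::CJ(cell_type = rownames(tp), metacell = rownames(mp))
  out[, r := {
    a <- tp[cell_type, ]; b <- mp[metacell, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, by = .(cell_type, metacell)]
  out[]
}

#' Tissue signatures from chromatin modules (with differential fallback)
#'
#' For every tissue with at least one associated module (per
#' [detect_modules()]), the signature is the union of the accessible sets of
#' the metacells in those modules. Tissues with no associated module fall
#' back to their top differential peaks versus the rest (ranked by p-value,
#' passing peaks capped at `top_n`).
#'
#' @param modules result of [detect_modules()].
#' @param metacell_sets named list: accessible peak set per metacell.
#' @param peak_matrix,tissue_labels needed only for the fallback path.
#' @param top_n fallback signature cap (default 500).
#' @param fdr,log2fc fallback marker cutoffs (defaults 0.1 / 0.5).
#' @return named list tissue -> peak id vector (a `TissueSignature`).
#' @export
build_tissue_signatures <- function(modules, metacell_sets,
                                    peak_matrix = NULL, tissue_labels = NULL,
                                    top_n = 500L, fdr = 0.1, log2fc = 0.5) {
  assoc <- modules$associations[associated == TRUE]
  tissues <- sort(unique(modules$associations$tissue))
  sig <- list()
  need_fallback <- character(0)
  for (t in tissues) {
    mods <- assoc[tissue == t, module]
    if (length(mods)) {
      mcs <- names(modules$modules)[modules$modules %in% mods]
      sig[[t]] <- sort(unique(unlist(metacell_sets[mcs])))
    } else {
      need_fallback <- c(need_fallback, t)
    }
  }
  if (length(need_fallback)) {
    if (is.null(peak_matrix) || is.null(tissue_labels)) {
      stopf("tissue(s) %s have no associated module and no fallback inputs",
            paste(need_fallback, collapse = ", "))
    }
    fb <- marker_signatures(peak_matrix, tissue_labels, top_n = top_n,
                            fdr = fdr, log2fc = log2fc)
    for (t in need_fallback) sig[[t]] <- fb[[t]]
  }
  if (!length(sig) || all(lengths(sig) == 0)) {
    stopf("no tissue acquired a signature")
  }
  sig
}

#' Marker-peak tissue signatures
#'
#' One signature per tissue: peaks passing the marker cutoffs in a
#' tissue-vs-rest Wilcoxon test, ranked by p-value and capped at `top_n`.
#' When nothing passes for a tissue, the `min_n` smallest-p peaks are used
#' so downstream scoring stays defined (on null data this yields
#' chance-level signatures, the intended negative-control behavior).
#'
#' @param peak_matrix a peak [feature_matrix()].
#' @param tissue_labels vector aligned with rows.
#' @param top_n,min_n signature size cap and floor.
#' @param fdr,log2fc marker cutoffs.
#' @return named list tissue -> peak ids.
#' @export
marker_signatures <- function(peak_matrix, tissue_labels, top_n = 500L,
                              min_n = 50L, fdr = 0.1, log2fc = 0.5) {
  mk <- marker_features(peak_matrix, tissue_labels, fdr = fdr,
                        log2fc = log2fc)
  sig <- list()
  for (t in sort(unique(as.character(tissue_labels)))) {
    sub <- mk[group == t][order(p_value, -log2fc)]
    pass <- sub[passes == TRUE]
    sig[[t]] <- if (nrow(pass)) utils::head(pass$feature, top_n)
                else utils::head(sub$feature, min_n)
  }
  sig
}

#' Predict tissue of origin from binarized peak profiles
#'
#' Scores every cell against every tissue signature with the Jaccard index
#' of the cell's nonzero peak set and the signature; the prediction is the
#' argmax (exact ties and empty profiles are unclassified).
#'
#' @param peak_matrix a peak [feature_matrix()] (rows = cells to classify).
#' @param signatures named list tissue -> peak ids (>= 2 signatures).
#' @param truth optional named vector barcode -> true tissue; adds an
#'   `accuracy` element computed over classified cells.
#' @return list with `prediction` (data.table: barcode, predicted, score),
#'   `scores` (cells x tissues matrix), and optionally `accuracy` and
#'   `n_unclassified`.
#' @export
predict_origin <- function(peak_matrix, signatures, truth = NULL) {
  if (length(signatures) < 2L) stopf("need at least 2 signatures")
  Bm <- peak_matrix$counts
  Bm@x <- rep(1, length(Bm@x))
  peaks <- colnames(Bm)
  S <- Matrix::sparseMatrix(
    i = unlist(lapply(signatures, function(s) match(intersect(s, peaks), peaks))),
    j = rep(seq_along(signatures),
            vapply(signatures, function(s) length(intersect(s, peaks)), 0L)),
    x = 1, dims = c(length(peaks), length(signatures)),
    dimnames = list(peaks, names(signatures)))
  inter <- as.matrix(Bm %*% S)
  cell_n <- Matrix::rowSums(Bm)
  sig_n <- Matrix::colSums(S)
  uni <- outer(cell_n, rep(1, length(sig_n))) +
    outer(rep(1, length(cell_n)), sig_n) - inter
  scores <- ifelse(uni > 0, inter / uni, 0)
  dimnames(scores) <- list(rownames(Bm), names(signatures))
  best <- apply(scores, 1L, function(r) {
    m <- max(r)
    if (sum(r == m) != 1L) NA_integer_ else which.max(r)
  })
  pred <- data.table::data.table(
    barcode = rownames(Bm),
    predicted = ifelse(is.na(best), NA_character_, colnames(scores)[best]),
    score = ifelse(is.na(best), NA_real_, scores[cbind(seq_len(nrow(scores)),
                                                       pmax(best, 1L))]))
  pred[cell_n == 0, predicted := NA_character_]
  out <- list(prediction = pred, scores = scores)
  if (!is.null(truth)) {
    cls <- !is.na(pred$predicted)
    out$n_unclassified <- sum(!cls)
    out$accuracy <- if (any(cls)) {
      mean(pred$predicted[cls] == truth[pred$barcode[cls]])
    } else NA_real_
  }
  out
}

#' Held-out tissue-of-origin tracing
#'
#' The headline experiment: splits the given cells into seeded train/test
#' halves, builds per-tissue marker-peak signatures from the training half
#' only, and predicts the tissue of origin of the held-out half by Jaccard
#' scoring. With tissue-level peaks planted, stromal cells are traced back
#' to their organ; with none, accuracy drops to chance (1 / n_tissues).
#'
#' @param peak_matrix a peak [feature_matrix()].
#' @param tissue_labels named vector barcode -> tissue.
#' @param cells barcodes to use (e.g. stromal cells only); default all rows.
#' @param split_fraction training fraction (default 0.5).
#' @param seed split seed.
#' @param top_n,fdr,log2fc signature parameters (see [marker_signatures()]).
#' @return list with `accuracy`, `prediction`, `signatures`, `train`,
#'   `test`, `n_unclassified`.
#' @export
trace_tissue_of_origin <- function(peak_matrix, tissue_labels, cells = NULL,
                                   split_fraction = 0.5, seed = 1L,
                                   top_n = 500L, fdr = 0.1, log2fc = 0.5) {
  cells <- cells %||% rownames(peak_matrix$counts)
  train <- with_seed(seed, {
    unlist(lapply(split(cells, tissue_labels[cells]), function(b)
      sample(b, max(1L, round(length(b) * split_fraction)))))
  })
  test <- setdiff(cells, train)
  if (!length(test)) stopf("held-out set is empty")
  tr_mat <- feature_matrix(peak_matrix$counts[train, , drop = FALSE],
                           flavor = "peak",
                           depth = peak_matrix$depth[train])
  sig <- marker_signatures(tr_mat, tissue_labels[train], top_n = top_n,
                           fdr = fdr, log2fc = log2fc)
  te_mat <- feature_matrix(peak_matrix$counts[test, , drop = FALSE],
                           flavor = "peak",
                           depth = peak_matrix$depth[test])
  res <- predict_origin(te_mat, sig, truth = tissue_labels)
  list(accuracy = res$accuracy, prediction = res$prediction,
       signatures = sig, train = train, test = test,
       n_unclassified = res$n_unclassified)
}

#' Combinatorial region + gene gating
#'
#' Selects cells whose (imputed) accessibility at one region exceeds
#' `region_threshold` and whose activity score for one gene exceeds
#' `gene_threshold` (both strict), emulating a two-channel sort that
#' combines a tissue-specific accessible region with a cell-type marker
#' gene.
#'
#' @param region_values named numeric vector (barcode -> region
#'   accessibility, typically imputed).
#' @param gene_values named numeric vector (barcode -> gene score), same
#'   cells.
#' @param region_threshold,gene_threshold strict lower cutoffs; default the
#'   75th percentile of each feature's positive values (for a sparse
#'   feature, a percentile over all cells sits in the zero/noise floor and
#'   admits any leakage; restricting to detected cells makes the default
#'   scale-adaptive).
#' @return character vector of selected barcodes.
#' @export
combinatorial_gate <- function(region_values, gene_values,
                               region_threshold = NULL,
                               gene_threshold = NULL) {
  stopifnot(length(region_values) == length(gene_values))
  q75_pos <- function(v) {
    pos <- v[v > 0]
    stats::quantile(if (length(pos)) pos else v, 0.75, names = FALSE)
  }
  region_threshold <- region_threshold %||% q75_pos(region_values)
  gene_threshold <- gene_threshold %||% q75_pos(gene_values)
  sel <- region_values > region_threshold & gene_values > gene_threshold
  names(region_values)[sel]
}

#' Correlation between two per-cell signals
#'
#' Spearman (Pearson on mid-ranks, tie-handled) or Pearson correlation with
#' a t-approximation p-value on n - 2 degrees of freedom; for n <= 8 the
#' p-value is computed by exact permutation instead.
#'
#' @param values_x,values_y paired finite numeric vectors, n >= 3.
#' @param method "spearman" (default) or "pearson".
#' @return list with `coefficient` and `p_value`.
#' @export
marker_correlation <- function(values_x, values_y,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(values_x) & is.finite(values_y)
  x <- values_x[ok]; y <- values_y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance in one of the vectors")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho <- stats::cor(x, y)
  if (n <= 8L) {
    perms <- perm_all(n)
    ref <- apply(perms, 1L, function(p) stats::cor(x, y[p]))
    p <- mean(abs(ref) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(coefficient = rho, p_value = min(p, 1))
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
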