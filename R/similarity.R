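#' Binarized accessible peak set of a cell group
#'
#' A peak belongs to a group's accessible set iff it is nonzero in at least
#' `min_fraction` of the group's cells.
#'
#' @param peak_matrix a peak [feature_matrix()].
#' @param cells barcodes of the group (non-empty).
#' @param min_fraction detection fraction cutoff (default 0.05).
#' @return character vector of peak ids (an `AccessibleSet`), with the
#'   fraction cutoff attached as an attribute.
#' @export
accessible_set <- function(peak_matrix, cells, min_fraction = 0.05) {
  if (!length(cells)) stopf("empty group")
  sub <- peak_matrix$counts[cells, , drop = FALSE]
  frac <- Matrix::colSums(sub > 0) / length(cells)
  structure(colnames(sub)[frac >= min_fraction], min_fraction = min_fraction)
}

#' Jaccard similarity matrix between sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; two empty sets get 0 (logged).
#'
#' @param sets named list of character vectors (peak ids).
#' @return symmetric matrix of Jaccard indices, diagonal 1 for non-empty
#'   sets.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2L) stopf("need at least 2 sets")
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  M <- Matrix::sparseMatrix(
    i = unlist(lapply(sets, function(s) match(unique(s), universe))),
    j = rep(seq_along(sets), vapply(sets, function(s) length(unique(s)), 0L)),
    x = 1, dims = c(length(universe), length(sets)))
  inter <- as.matrix(Matrix::crossprod(M))
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  both_empty <- uni == 0
  if (any(both_empty[upper.tri(both_empty)])) {
    message("Jaccard of two empty sets defined as 0")
  }
  J <- ifelse(uni > 0, inter / uni, 0)
  dimnames(J) <- list(nm, nm)
  J
}

#' Mean intra-cell-type Jaccard similarity
#'
#' For each cell type, builds one accessible set per (type, tissue)
#' pseudo-group with at least `min_cells` cells and reports the mean over
#' all pairwise Jaccard indices among those sets. Types present in a single
#' tissue are scored by splitting their cells into two random halves
#' (seeded), so every type gets a comparable within-type reproducibility
#' value. Shared stromal types that carry divergent tissue-level peaks score
#' lower than organ-restricted types.
#'
#' @param peak_matrix a peak [feature_matrix()].
#' @param barcodes,type_labels,tissue_labels aligned per-cell vectors.
#' @param min_fraction accessible-set cutoff.
#' @param min_cells minimum pseudo-group size (default 20).
#' @param seed seed for pseudo-replicate splits.
#' @return data.table (cell_type, mean_jaccard, n_groups).
#' @export
intra_type_similarity <- function(peak_matrix, barcodes, type_labels,
                                  tissue_labels, min_fraction = 0.05,
                                  min_cells = 20L, seed = 1L) {
  dt <- data.table::data.table(barcode = barcodes, type = type_labels,
                               tissue = tissue_labels)
  out <- list()
  for (ty in sort(unique(dt$type))) {
    sub <- dt[type == ty]
    if (nrow(sub) < min_cells) {
      stopf("cell type '%s' has fewer than %d cells", ty, min_cells)
    }
    grp <- split(sub$barcode, sub$tissue)
    grp <- grp[lengths(grp) >= min_cells]
    if (length(grp) < 2L) {
      # single-tissue type: two seeded pseudo-replicate halves
      bcs <- sub$barcode
      half <- with_seed(seed, sample(bcs, length(bcs) %/% 2L))
      grp <- list(half1 = half, half2 = setdiff(bcs, half))
    }
    sets <- lapply(grp, function(b)
      accessible_set(peak_matrix, b, min_fraction))
    J <- jaccard_matrix(sets)
    out[[ty]] <- data.table::data.table(
      cell_type = ty, mean_jaccard = mean(J[upper.tri(J)]),
      n_groups = length(sets))
  }
  data.table::rbindlist(out)
}

#' Detect chromatin modules in a metacell similarity matrix
#'
#' Average-linkage hierarchical clustering on distance `1 - J`, cut into
#' `n_modules`; each (module, tissue) pair is tested for overrepresentation
#' of that tissue's majority-metacells by the hypergeometric upper tail, with
#' BH FDR across all module x tissue tests. Associations are declared at
#' `fdr < 0.05`.
#'
#' @param similarity symmetric Jaccard matrix over metacells (names =
#'   metacell ids).
#' @param majority_tissue named vector: majority tissue per metacell.
#' @param n_modules number of modules (default: number of distinct tissues).
#' @return list with `modules` (named integer vector metacell -> module) and
#'   `associations` (data.table: module, tissue, overlap, module_size,
#'   tissue_size, p, fdr, associated).
#' @export
detect_modules <- function(similarity, majority_tissue, n_modules = NULL) {
  n <- nrow(similarity)
  n_modules <- n_modules %||% length(unique(majority_tissue))
  if (n_modules > n) stopf("n_modules (%d) exceeds metacell count (%d)",
                           n_modules, n)
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  mod <- stats::cutree(hc, k = n_modules)
  names(mod) <- rownames(similarity)
  tis <- majority_tissue[names(mod)]
  tests <- data.table::CJ(module = sort(unique(mod)),
                          tissue = sort(unique(tis)))
  tests[, c("overlap", "module_size", "tissue_size") :=
          .(sum(mod == module & tis == tissue), sum(mod == module),
            sum(tis == tissue)),
        by = .(module, tissue)]
  tests[, p := stats::phyper(overlap - 1L, tissue_size, n - tissue_size,
                             module_size, lower.tail = FALSE)]
  tests[, fdr := bh_fdr(p)]
  tests[, associated := fdr < 0.05]
  list(modules = mod, associations = tests[])
}
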