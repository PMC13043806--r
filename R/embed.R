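#' TF-IDF normalization for scATAC count matrices
#'
#' Binarizes the counts, computes term frequency `TF(i,j)` as the cell-wise
#' fraction of detected features, inverse document frequency
#' `IDF(j) = ln(1 + n_cells / (1 + n_cells_with_feature_j))`, and returns
#' `X(i,j) = ln(1 + 1e4 * TF * IDF)`. Zeros are preserved, so the result
#' stays sparse. Cells with no counts in the selected features are dropped
#' with a warning.
#'
#' @param matrix a [feature_matrix()] or sparse matrix with dimnames.
#' @param features optional character vector (or integer indices) of columns
#'   to use; default all.
#' @param idf optional precomputed IDF vector (used when projecting new cells
#'   into an existing model); default computed from `matrix`.
#' @return list with `X` (sparse normalized matrix over selected features),
#'   `idf`, `features`, `dropped` (barcodes removed).
#' @export
tfidf_transform <- function(matrix, features = NULL, idf = NULL) {
  counts <- if (inherits(matrix, "feature_matrix")) matrix$counts else matrix
  if (!is.null(features)) counts <- counts[, features, drop = FALSE]
  bin <- counts
  bin@x <- rep(1, length(bin@x))
  rs <- Matrix::rowSums(bin)
  dropped <- rownames(bin)[rs == 0]
  if (length(dropped)) {
    warnf("dropping %d cell(s) with no counts in the selected features",
          length(dropped))
    bin <- bin[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  n <- nrow(bin)
  if (is.null(idf)) {
    df <- Matrix::colSums(bin)
    idf <- log(1 + n / (1 + df))
    names(idf) <- colnames(bin)
  }
  X <- Matrix::Diagonal(x = 1 / rs) %*% bin %*% Matrix::Diagonal(x = idf)
  X <- methods::as(X, "CsparseMatrix")
  X@x <- log1p(1e4 * X@x)
  dimnames(X) <- dimnames(bin)
  list(X = X, idf = idf, features = colnames(bin), dropped = dropped)
}

#' Truncated SVD (LSI) embedding with depth-correlated dimension removal
#'
#' Computes the top `n_dims` singular triplets of the TF-IDF matrix; cell
#' coordinates are the left singular vectors scaled by the singular values.
#' Any dimension whose coordinates correlate with log depth beyond
#' `depth_cor_cutoff` in absolute Pearson r is dropped from the kept mask
#' (these dimensions track library size, not biology). Basis column signs are
#' fixed by making each column's largest-magnitude loading positive.
#'
#' @param X normalized sparse matrix from [tfidf_transform()].
#' @param n_dims number of singular vectors (default 30); values at or above
#'   the matrix rank fall back to a rank-limited exact decomposition with a
#'   warning.
#' @param depth per-cell total fragment depth aligned with `rows(X)`; NULL
#'   disables the correlation filter.
#' @param depth_cor_cutoff absolute Pearson r above which a dimension is
#'   dropped (default 0.75).
#' @param seed seed for the randomized solver.
#' @return list with `model` (an `lsi_model`: basis, singular values, kept
#'   mask, idf/features slots filled by [fit_lsi()]) and `embedding` (cells x
#'   kept-dims coordinate matrix).
#' @export
svd_embed <- function(X, n_dims = 30L, depth = NULL, depth_cor_cutoff = 0.75,
                      seed = 1L) {
  n_dims <- as.integer(n_dims)
  maxrank <- min(dim(X))
  k <- min(n_dims, maxrank)
  if (k < n_dims) {
    warnf("n_dims = %d exceeds matrix rank bound %d; returning %d dimensions",
          n_dims, maxrank, k)
  }
  dec <- if (k >= maxrank - 1L || k < 3L) {
    s <- svd(as.matrix(X), nu = k, nv = k)
    list(u = s$u[, seq_len(k), drop = FALSE],
         v = s$v[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)])
  } else {
    with_seed(seed, irlba::irlba(X, nv = k))
  }
  # sign convention: largest-magnitude loading of each basis column positive
  flip <- vapply(seq_len(k), function(j) {
    v <- dec$v[, j]
    sign(v[which.max(abs(v))]) < 0
  }, NA)
  dec$v[, flip] <- -dec$v[, flip, drop = FALSE]
  dec$u[, flip] <- -dec$u[, flip, drop = FALSE]

  coords <- dec$u %*% diag(dec$d, k, k)
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("LSI", seq_len(k))

  keep <- rep(TRUE, k)
  if (!is.null(depth)) {
    ld <- log(pmax(depth, 1))
    r <- vapply(seq_len(k), function(j) {
      if (stats::sd(coords[, j]) == 0 || stats::sd(ld) == 0) return(0)
      stats::cor(coords[, j], ld)
    }, 0)
    keep <- abs(r) <= depth_cor_cutoff
    if (!any(keep)) {
      warnf("all dimensions correlate with depth beyond %.2f; keeping dim with lowest |r|",
            depth_cor_cutoff)
      keep[which.min(abs(r))] <- TRUE
    }
  }
  model <- structure(list(basis = dec$v, d = dec$d, keep = keep,
                          features = colnames(X), idf = NULL),
                     class = "lsi_model")
  list(model = model, embedding = coords[, keep, drop = FALSE])
}

#' Fit TF-IDF + LSI in one step
#'
#' @param matrix a [feature_matrix()].
#' @param features columns to use (default all).
#' @param n_dims,depth_cor_cutoff,seed see [svd_embed()].
#' @return as [svd_embed()], with `idf` stored in the model so new cells can
#'   be projected via [project_lsi()].
#' @export
fit_lsi <- function(matrix, features = NULL, n_dims = 30L,
                    depth_cor_cutoff = 0.75, seed = 1L) {
  tf <- tfidf_transform(matrix, features)
  depth <- matrix$depth[rownames(tf$X)]
  res <- svd_embed(tf$X, n_dims = n_dims, depth = depth,
                   depth_cor_cutoff = depth_cor_cutoff, seed = seed)
  res$model$idf <- tf$idf
  res$dropped <- tf$dropped
  res
}

#' Project cells into a fitted LSI model
#'
#' Applies the stored feature selection and IDF to new count rows and maps
#' them onto the kept LSI dimensions (`X V`, the coordinates the training
#' cells received).
#'
#' @param model an `lsi_model` from [fit_lsi()].
#' @param counts sparse count matrix (cells x full feature universe) with
#'   dimnames.
#' @return matrix of cells x kept-dims coordinates.
#' @export
project_lsi <- function(model, counts) {
  if (is.null(model$idf)) stopf("model has no stored IDF; fit with fit_lsi()")
  counts <- if (inherits(counts, "feature_matrix")) counts$counts else counts
  bin <- counts[, model$features, drop = FALSE]
  bin <- methods::as(bin, "CsparseMatrix")
  bin@x <- rep(1, length(bin@x))
  rs <- pmax(Matrix::rowSums(bin), 1)
  X <- Matrix::Diagonal(x = 1 / rs) %*% bin %*% Matrix::Diagonal(x = model$idf)
  X <- methods::as(X, "CsparseMatrix")
  X@x <- log1p(1e4 * X@x)
  coords <- as.matrix(X %*% model$basis)
  rownames(coords) <- rownames(counts)
  colnames(coords) <- paste0("LSI", seq_len(ncol(coords)))
  coords[, model$keep, drop = FALSE]
}

#' Iterative LSI embedding
#'
#' Runs `lsi.iterations` rounds of LSI (default 4). Iteration 1 selects the
#' top `lsi.n_variable_features` features by total count; each later
#' iteration clusters the previous embedding at the next resolution in
#' `lsi.resolutions` (0.1, 0.2, 0.4), forms per-cluster pseudobulk sums,
#' depth-normalizes them to counts-per-10k and `ln(1+x)`, re-selects the top
#' features by cross-cluster variance, and re-embeds. If clustering yields
#' fewer than 2 clusters the feature set is carried forward unchanged.
#'
#' @param matrix a tile [feature_matrix()] over QC-retained cells.
#' @param config a [pipeline_config()].
#' @return list with `model`, `embedding`, `clusters` (final iteration's
#'   cluster labels), `feature_history`, and `iterations`.
#' @export
iterative_lsi <- function(matrix, config = pipeline_config()) {
  counts <- matrix$counts
  n_feat <- ncol(counts)
  n_target <- min(config$lsi.n_variable_features, n_feat)
  total <- Matrix::colSums(counts)
  feats <- colnames(counts)[order(total, decreasing = TRUE)[seq_len(n_target)]]
  history <- list(feats)
  res <- NULL; clusters <- NULL
  for (it in seq_len(config$lsi.iterations)) {
    if (it > 1L) {
      resol <- config$lsi.resolutions[it - 1L]
      clusters <- snn_cluster(res$embedding,
                              k_param = min(config$cluster.k_param,
                                            nrow(res$embedding) - 1L),
                              resolution = resol,
                              max_clusters = config$cluster.max_clusters,
                              seed = config$seed + it)
      if (length(unique(clusters)) < 2L) {
        message(sprintf("iteration %d: <2 clusters at resolution %.2f; feature set unchanged",
                        it, resol))
      } else {
        sub <- counts[rownames(res$embedding), , drop = FALSE]
        ps <- rowsum_sparse(sub, clusters)
        ps <- log1p(ps / pmax(rowSums(ps), 1) * 1e4)
        v <- matrixStats::colVars(ps)
        feats <- colnames(counts)[order(v, decreasing = TRUE)[seq_len(n_target)]]
      }
      history[[it]] <- feats
    }
    res <- fit_lsi(matrix, features = feats, n_dims = config$lsi.n_dims,
                   depth_cor_cutoff = config$lsi.depth_cor_cutoff,
                   seed = config$seed + it)
  }
  list(model = res$model, embedding = res$embedding, clusters = clusters,
       feature_history = history, iterations = config$lsi.iterations)
}

# dense per-group column sums of a sparse matrix
rowsum_sparse <- function(m, groups) {
  g <- as.factor(groups)
  ind <- Matrix::sparseMatrix(i = as.integer(g), j = seq_len(nrow(m)), x = 1,
                              dims = c(nlevels(g), nrow(m)))
  out <- as.matrix(ind %*% m)
  rownames(out) <- levels(g)
  out
}

#' Per-dimension batch location/scale adjustment
#'
#' For every kept embedding dimension, each batch is centered at the global
#' mean and its standard deviation rescaled to the pooled within-batch
#' standard deviation. Identity for a single batch; batches with fewer than
#' 2 cells are centered only.
#'
#' @param embedding cells x dims matrix.
#' @param batch vector of batch labels aligned with rows.
#' @return adjusted embedding.
#' @export
batch_adjust <- function(embedding, batch) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 1L) stopf("need at least one batch")
  if (nlevels(batch) == 1L) return(embedding)
  out <- embedding
  for (j in seq_len(ncol(embedding))) {
    x <- embedding[, j]
    gm <- mean(x)
    vs <- tapply(x, batch, stats::var)
    ns <- tabulate(batch)
    ok <- ns >= 2L
    sd_pool <- sqrt(sum(vs[ok] * (ns[ok] - 1L)) / max(sum(ns[ok] - 1L), 1L))
    for (b in levels(batch)) {
      i <- batch == b
      xb <- x[i] - mean(x[i])
      sb <- stats::sd(x[i])
      if (sum(i) >= 2L && is.finite(sb) && sb > 0 && sd_pool > 0) {
        xb <- xb / sb * sd_pool
      }
      out[i, j] <- xb + gm
    }
  }
  out
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a `k_param`-NN graph in the embedding (Euclidean), weights each
#' edge by the Jaccard overlap of the two cells' neighbor sets (self
#' included), prunes edges below 1/15, and optimizes modularity
#' (Louvain) at the given resolution. If more than `max_clusters` communities
#' result, the smallest cluster is iteratively merged into the cluster with
#' the nearest centroid.
#'
#' @param embedding cells x dims matrix with rownames.
#' @param k_param neighbors (default 30).
#' @param resolution Louvain resolution (default 1).
#' @param max_clusters hard cap on cluster count (default 60).
#' @param seed RNG seed for the modularity optimizer.
#' @param prune SNN weight cutoff (default 1/15).
#' @return integer cluster ids (1..C) named by barcode.
#' @export
snn_cluster <- function(embedding, k_param = 30L, resolution = 1,
                        max_clusters = 60L, seed = 1L, prune = 1 / 15) {
  n <- nrow(embedding)
  if (k_param >= n) stopf("k_param (%d) must be < number of cells (%d)", k_param, n)
  nn <- FNN::get.knn(embedding, k = k_param)$nn.index
  # neighbor-set membership incl. self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k_param + 1L),
                            j = c(seq_len(n), as.vector(nn)), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  shared <- Matrix::tcrossprod(A)
  tri <- Matrix::triu(shared, k = 1)
  sm <- Matrix::summary(tri)
  jac <- sm$x / (2 * (k_param + 1L) - sm$x)
  keep <- jac >= prune
  if (!any(keep)) {
    cl <- rep(1L, n)
    names(cl) <- rownames(embedding)
    return(cl)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sm$i[keep], to = sm$j[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  cl <- as.integer(igraph::membership(comm))

  while (length(unique(cl)) > max_clusters) {
    sizes <- table(cl)
    smallest <- as.integer(names(sizes)[which.min(sizes)])
    cents <- rowsum_dense(embedding, cl)
    cents <- cents / as.vector(table(cl)[rownames(cents)])
    d <- as.matrix(stats::dist(cents))[as.character(smallest), ]
    d[as.character(smallest)] <- Inf
    target <- as.integer(names(d)[which.min(d)])
    cl[cl == smallest] <- target
  }
  cl <- as.integer(factor(cl, levels = sort(unique(cl))))
  names(cl) <- rownames(embedding)
  cl
}

rowsum_dense <- function(m, groups) {
  out <- rowsum(m, groups)
  out
}
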