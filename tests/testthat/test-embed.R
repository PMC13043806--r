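test_that("TF-IDF matches the closed-form evaluation on a toy matrix", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2), x = c(3, 1, 5),
                            dims = c(2, 3),
                            dimnames = list(c("c1", "c2"),
                                            c("f1", "f2", "f3")))
  tf <- tfidf_transform(feature_matrix(m, "tile"))
  # independent hand computation of the stated formula
  bin <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  TF <- bin / rowSums(bin)
  IDF <- log(1 + 2 / (1 + colSums(bin)))
  X <- log1p(1e4 * sweep(TF, 2, IDF, "*"))
  expect_equal(as.matrix(tf$X), X, ignore_attr = TRUE, tolerance = 1e-12)
  # zeros preserved
  expect_equal(as.matrix(tf$X)[2, 1], 0)
  # a feature present in every cell has the minimal IDF ~ ln 2
  mm <- Matrix::sparseMatrix(i = c(1:4, 1), j = c(1, 1, 1, 1, 2), x = 1,
                             dims = c(4, 2),
                             dimnames = list(paste0("c", 1:4), c("all", "one")))
  tf2 <- tfidf_transform(feature_matrix(mm, "tile"))
  expect_equal(unname(tf2$idf["all"]), log(1 + 4 / 5))
  expect_equal(unname(which.min(tf2$idf)), 1L)
  # zero-count cells are dropped with a warning
  m0 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 2),
                             dimnames = list(c("c1", "c2"), c("f1", "f2")))
  expect_warning(r <- tfidf_transform(feature_matrix(m0, "tile")), "dropping")
  expect_identical(r$dropped, "c2")
})

test_that("svd_embed truncates, fixes signs, drops depth dimensions", {
  set.seed(3)
  # rank-2 matrix: singular values beyond 2 are ~0 (rank-limited fallback)
  u <- matrix(rnorm(40), 20, 2); v <- matrix(rnorm(16), 8, 2)
  X <- u %*% t(v)
  dimnames(X) <- list(paste0("c", 1:20), paste0("f", 1:8))
  res <- svd_embed(methods::as(X, "CsparseMatrix"), n_dims = 8)
  expect_lt(res$model$d[3] / res$model$d[1], 1e-10)
  expect_warning(svd_embed(methods::as(X, "CsparseMatrix"), n_dims = 9),
                 "rank")
  # orthonormal basis, sign convention: max-|loading| positive
  B <- res$model$basis
  expect_equal(crossprod(B[, 1:2]), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:2) expect_gt(B[which.max(abs(B[, j])), j], 0)

  # a dimension equal to depth is dropped at |r| > 0.75
  depth <- exp(seq(1, 4, length.out = 20))
  X2 <- outer(log(depth), c(2, 1, 1, 0.5)) +
    matrix(rnorm(80, sd = 0.01), 20, 4)
  dimnames(X2) <- list(paste0("c", 1:20), paste0("f", 1:4))
  r2 <- suppressWarnings(svd_embed(methods::as(X2, "CsparseMatrix"),
                                   n_dims = 3, depth = depth))
  expect_false(r2$model$keep[1])

  # reconstruction error non-increasing in n_dims (full-decomposition oracle)
  set.seed(8)
  Y <- matrix(rnorm(50 * 40), 50, 40)
  dimnames(Y) <- list(paste0("c", 1:50), paste0("f", 1:40))
  sv <- svd(Y)
  errs <- vapply(1:10, function(k) {
    rec <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sum((Y - rec)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
  r3 <- svd_embed(methods::as(Y, "CsparseMatrix"), n_dims = 10)
  expect_equal(r3$model$d[1:10], sv$d[1:10], tolerance = 1e-6)
})

test_that("iterative LSI with a vacuous feature cap equals plain LSI", {
  ds <- small_dataset()
  pc <- pipeline_config()
  qc <- qc_metrics(ds$fragments, ds$truth$genes, pc)
  keep <- filter_cells(qc, pc)
  tm <- make_tile_matrix(ds$fragments[barcode %in% keep], ds$config$genome,
                         5000, barcodes = keep)
  res <- iterative_lsi(tm, pc)
  # every iteration's feature set is a size-N subset of the tile universe
  n_target <- min(pc$lsi.n_variable_features, ncol(tm$counts))
  for (fs in res$feature_history) {
    expect_length(fs, n_target)
    expect_true(all(fs %in% colnames(tm$counts)))
  }
  # n_features < cap: all features selected, result equals one LSI fit on
  # the same (vacuously selected) feature set
  single <- fit_lsi(tm, features = res$feature_history[[pc$lsi.iterations]],
                    n_dims = pc$lsi.n_dims,
                    depth_cor_cutoff = pc$lsi.depth_cor_cutoff,
                    seed = pc$seed + pc$lsi.iterations)
  expect_equal(res$embedding, single$embedding, tolerance = 1e-8)
})

test_that("batch adjustment aligns location and scale per dimension", {
  set.seed(4)
  emb <- matrix(rnorm(60), 30, 2,
                dimnames = list(paste0("c", 1:30), NULL))
  # identity for one batch
  expect_identical(batch_adjust(emb, rep("x", 30)), emb)
  # constant offset between two batches vanishes
  batch <- rep(c("a", "b"), each = 15)
  shifted <- emb
  shifted[batch == "b", ] <- shifted[batch == "b", ] + 5
  adj <- batch_adjust(shifted, batch)
  expect_lt(abs(mean(adj[batch == "a", 1]) - mean(adj[batch == "b", 1])), 1e-10)
  expect_lt(abs(mean(adj[batch == "a", 2]) - mean(adj[batch == "b", 2])), 1e-10)
  # planted batch shift on 2-cluster data: recovery improves after adjustment
  cl <- rep(c(1, 2), 20)
  emb2 <- matrix(rnorm(80, sd = 0.3), 40, 2) + cbind(3 * cl, 0)
  b2 <- rep(c("a", "b"), each = 20)
  emb2[b2 == "b", 2] <- emb2[b2 == "b", 2] + 8
  k_raw <- stats::kmeans(emb2, 2, nstart = 10)$cluster
  k_adj <- stats::kmeans(batch_adjust(emb2, b2), 2, nstart = 10)$cluster
  acc <- function(k) max(mean(k == cl), mean(k == 3 - cl))
  expect_gt(acc(k_adj), acc(k_raw))
})

test_that("SNN clustering separates blobs, caps cluster count, is seeded", {
  set.seed(11)
  blob <- function(mu, n) sweep(matrix(rnorm(n * 2, sd = 0.2), n, 2), 2, mu, "+")
  emb <- rbind(blob(c(0, 0), 150), blob(c(10, 10), 150))
  rownames(emb) <- paste0("c", 1:300)
  truth <- rep(1:2, each = 150)
  cl <- snn_cluster(emb, k_param = 50, resolution = 1, seed = 3)
  expect_equal(length(unique(cl)), 2L)
  tab <- table(cl, truth)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 300)  # purity 1
  # determinism
  expect_identical(cl, snn_cluster(emb, k_param = 50, resolution = 1, seed = 3))
  # all points identical -> one cluster
  same <- matrix(1, 50, 2, dimnames = list(paste0("c", 1:50), NULL))
  expect_equal(length(unique(snn_cluster(same, k_param = 10))), 1L)
  # max_clusters honored by centroid merging
  set.seed(12)
  many <- do.call(rbind, lapply(1:8, function(i) blob(c(5 * i, 0), 40)))
  rownames(many) <- paste0("c", seq_len(nrow(many)))
  cl8 <- snn_cluster(many, k_param = 10, resolution = 2, max_clusters = 3,
                     seed = 1)
  expect_lte(length(unique(cl8)), 3L)
  expect_error(snn_cluster(emb, k_param = 500), "k_param")
})

test_that("iterative LSI separates planted populations on default-scale data", {
  run <- default_run()
  info <- cell_info(run, rownames(run$lsi$embedding))
  lab <- paste(info$tissue, info$cell_type)
  cl <- snn_cluster(run$lsi$embedding, k_param = 30, resolution = 1,
                    max_clusters = 60, seed = 202)
  # contingency-based agreement with the generative populations
  tab <- table(cl, lab)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.85)
  ari <- adjusted_rand(cl, lab)
  expect_gte(ari, 0.9)
})
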