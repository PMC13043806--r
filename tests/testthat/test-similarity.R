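test_that("accessible sets apply the detection-fraction cutoff exactly", {
  set.seed(14)
  m <- Matrix::Matrix(0, 100, 3, sparse = TRUE,
                      dimnames = list(paste0("c", 1:100), c("p1", "p2", "p3")))
  m[1:4, 1] <- 1     # 4% of cells
  m[1:5, 2] <- 1     # 5% of cells
  m[1, 3] <- 3
  fm <- feature_matrix(m, "peak")
  cells <- rownames(m)
  expect_setequal(accessible_set(fm, cells, min_fraction = 0.05), "p2")
  expect_setequal(accessible_set(fm, cells, min_fraction = 0),
                  c("p1", "p2", "p3"))
  expect_setequal(accessible_set(fm, "c1", min_fraction = 0.5),
                  c("p1", "p2", "p3"))
  expect_error(accessible_set(fm, character(0)), "empty")
})

test_that("Jaccard matrices match the brute-force set oracle", {
  expect_equal(jaccard_matrix(list(a = c("p1", "p2", "p3"),
                                   b = c("p2", "p3", "p4")))["a", "b"], 0.5)
  J <- jaccard_matrix(list(x = c("p1"), y = c("p1"), z = c("p9")))
  expect_equal(J["x", "y"], 1)
  expect_equal(J["x", "z"], 0)
  expect_equal(diag(J), c(x = 1, y = 1, z = 1))

  set.seed(6)
  for (rep in 1:10) {
    universe <- paste0("p", 1:100)
    sets <- lapply(1:6, function(i) sample(universe, rpois(1, 20)))
    names(sets) <- letters[1:6]
    expect_equal(jaccard_matrix(sets), oracle_jaccard(sets))
  }
  # both-empty pairs are 0 by convention
  suppressMessages(J0 <- jaccard_matrix(list(a = character(), b = character())))
  expect_equal(J0["a", "b"], 0)
})

test_that("intra-type similarity is high for replicate halves and lower for stromal types", {
  run <- default_run()
  pm <- run$peak_matrix
  info <- cell_info(run, rownames(pm$counts))
  keep <- !info$is_doublet & !info$is_lowq
  sub <- feature_matrix(pm$counts[keep, ], "peak", pm$depth[keep])
  bcs <- rownames(sub$counts)
  ity <- intra_type_similarity(sub, bcs, info$cell_type[keep],
                               info$tissue[keep], seed = 9)
  stromal <- c("endothelial", "fibroblast", "macrophage")
  s_mean <- ity[cell_type %in% stromal, mean_jaccard]
  r_mean <- ity[!cell_type %in% stromal, mean_jaccard]
  # single-tissue types (replicate halves) reproduce well; every stromal
  # type is strictly below every organ-restricted type
  expect_gt(min(r_mean), 0.7)
  expect_lt(max(s_mean), min(r_mean))

  # one-sided permutation test over the type-class labeling
  obs <- mean(r_mean) - mean(s_mean)
  all_vals <- ity$mean_jaccard
  is_stromal <- ity$cell_type %in% stromal
  combs <- utils::combn(length(all_vals), sum(is_stromal))
  ref <- apply(combs, 2L, function(idx)
    mean(all_vals[-idx]) - mean(all_vals[idx]))
  p <- mean(ref >= obs - 1e-12)
  expect_lt(p, 0.01)

  expect_error(intra_type_similarity(sub, bcs[1:5], rep("t", 5), rep("x", 5)),
               "fewer than")
})

test_that("module detection cuts blocks and associates tissues hypergeometrically", {
  # block-diagonal similarity: two perfect blocks force the partition
  J <- matrix(0, 10, 10, dimnames = list(paste0("m", 1:10), paste0("m", 1:10)))
  J[1:5, 1:5] <- 0.9; J[6:10, 6:10] <- 0.9; diag(J) <- 1
  maj <- stats::setNames(rep(c("liver", "lung"), each = 5), rownames(J))
  mod <- detect_modules(J, maj, n_modules = 2)
  expect_equal(length(unique(mod$modules[1:5])), 1L)
  expect_equal(length(unique(mod$modules[6:10])), 1L)
  expect_true(mod$modules[1] != mod$modules[6])

  # a module holding all and only liver metacells: p is the minimal
  # hypergeometric tail 1/C(10,5)
  a <- mod$associations[overlap == 5 & module_size == 5 & tissue == "liver"]
  expect_equal(a$p, oracle_hyper_tail(5, 5, 10, 5))
  expect_equal(a$p, 1 / choose(10, 5))
  expect_true(all(mod$associations[overlap == 5, associated]))
  expect_error(detect_modules(J, maj, n_modules = 11), "exceeds")

  # shuffled labels: near-never associated at fdr < 0.05
  set.seed(50)
  n <- 40
  sim <- matrix(runif(n * n, 0, 0.2), n, n)
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  dimnames(sim) <- list(paste0("m", 1:n), paste0("m", 1:n))
  hitrate <- mean(vapply(1:100, function(i) {
    maj <- stats::setNames(sample(rep(paste0("t", 1:4), each = 10)),
                           rownames(sim))
    any(detect_modules(sim, maj, n_modules = 4)$associations$associated)
  }, NA))
  expect_lte(hitrate, 0.05)
})

test_that("stromal metacells are more similar within than between tissues", {
  run <- default_run()
  mc <- metacell_run()
  info <- cell_info(run, mc$assignment$assignment$barcode)
  tis <- stats::setNames(info$tissue, info$barcode)
  comp <- tissue_composition(mc$assignment$assignment, tis, n_metacells = 90)
  types <- stats::setNames(info$cell_type, info$barcode)
  tcomp <- tissue_composition(mc$assignment$assignment, types,
                              n_metacells = 90)
  stromal_mc <- names(tcomp$majority)[
    !is.na(tcomp$majority) &
      tcomp$majority %in% c("endothelial", "fibroblast", "macrophage")]
  stromal_mc <- stromal_mc[!is.na(comp$majority[stromal_mc])]
  asg <- mc$assignment$assignment

  gap <- vapply(c(0.01, 0.05, 0.1), function(mf) {
    sets <- lapply(stromal_mc, function(m)
      accessible_set(mc$pm, asg[metacell == as.integer(m), barcode], mf))
    names(sets) <- stromal_mc
    J <- jaccard_matrix(sets)
    same <- outer(comp$majority[stromal_mc], comp$majority[stromal_mc], "==")
    ut <- upper.tri(J)
    mean(J[ut & same]) - mean(J[ut & !same])
  }, 0)
  # qualitative ordering is stable across the detection-fraction range
  expect_true(all(gap > 0))

  # permutation test at the default fraction: shuffling tissue labels over
  # metacells abolishes the within-tissue excess
  sets <- lapply(stromal_mc, function(m)
    accessible_set(mc$pm, asg[metacell == as.integer(m), barcode], 0.05))
  names(sets) <- stromal_mc
  J <- jaccard_matrix(sets)
  maj <- comp$majority[stromal_mc]
  ut <- upper.tri(J)
  obs <- mean(J[ut & outer(maj, maj, "==")]) -
    mean(J[ut & !outer(maj, maj, "==")])
  ref <- chromtrace:::with_seed(17, vapply(1:200, function(i) {
    pm2 <- sample(maj)
    same2 <- outer(pm2, pm2, "==")
    mean(J[ut & same2]) - mean(J[ut & !same2])
  }, 0))
  expect_lt(mean(ref >= obs), 0.01)
})
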