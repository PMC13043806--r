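test_that("truth catalogs are deterministic, classed and placed without overlap", {
  cfg <- small_sim_config()
  t1 <- build_truth(cfg)
  t2 <- build_truth(cfg)
  expect_identical(t1$peaks, t2$peaks)
  expect_identical(t1$genes, t2$genes)

  counts <- t1$peaks[, .N, by = class]
  expect_equal(counts[class == "housekeeping", N], 50)
  expect_equal(counts[class == "tissue", N], 12 * 3)
  expect_equal(counts[class == "celltype", N], 12 * 6)  # 3 stromal + 3 restricted

  pk <- t1$peaks[order(chrom, start)]
  same <- pk$chrom[-1] == pk$chrom[-nrow(pk)]
  expect_true(all(!same | pk$start[-1] >= pk$end[-nrow(pk)]))

  # every cell-type peak has a paired gene within 25 kb (here: TSS on summit)
  ct <- t1$peaks[class == "celltype"]
  gn <- t1$genes[match(ct$peak_id, paired_peak)]
  expect_true(all(abs(gn$tss - ct$summit) <= 25000))

  # zero tissue peaks leaves only the other classes
  t0 <- build_truth(small_sim_config(n_tissue_peaks_per_tissue = 0))
  expect_setequal(unique(t0$peaks$class), c("housekeeping", "celltype"))

  # open-peak map: housekeeping open everywhere, tissue peaks tissue-wide
  g <- t1$groups[tissue == "liver"][1]
  open <- t1$peaks[t1$open_peaks[[g$group]]]
  expect_true(all(open[class == "tissue", owner] == "liver"))
  expect_equal(sum(open$class == "housekeeping"), 50)
})

test_that("capacity errors are raised when peaks cannot be placed", {
  cfg <- small_sim_config(genome = c(chr1 = 2e5), n_housekeeping_peaks = 500,
                          min_peak_separation_bp = 5000)
  expect_error(build_truth(cfg), "could not place")
})

test_that("simulated fragments follow the generative model", {
  ds <- small_dataset()
  cfg <- ds$config
  fr <- ds$fragments
  expect_true(all(fr$start >= 0))
  expect_true(all(fr$end > fr$start))
  expect_true(all(fr$end <= cfg$genome[fr$chrom]))
  # sorted by chromosome then start
  o <- order(match(fr$chrom, names(cfg$genome)), fr$start)
  expect_identical(o, seq_len(nrow(fr)))

  # same seed twice reproduces fragments byte-identically
  ds2 <- simulate_fragments(build_truth(cfg), cfg)
  expect_identical(ds$fragments, ds2$fragments)
  expect_identical(ds$cells, ds2$cells)

  # doublets union two real cells' fragment counts
  db <- ds$cells[is_doublet == TRUE]
  expect_true(all(db$partner_1 != db$partner_2))
  nf <- fr[, .N, by = barcode]
  one <- db[1]
  expect_equal(nf[barcode == one$barcode, N],
               nf[barcode == one$partner_1, N] + nf[barcode == one$partner_2, N])

  # low-quality cells draw background only: no enrichment at planted peaks
  lq <- ds$cells[is_lowq == TRUE, barcode]
  peak_bp <- nrow(ds$truth$peaks) * cfg$peak_width_bp
  frac <- frac_overlapping(fr[barcode %in% lq], ds$truth$peaks)
  expect_lt(frac, 3 * peak_bp / sum(cfg$genome))
})

test_that("observed in-peak fraction tracks signal_fraction", {
  # ~200 normal cells at default signal strength
  cfg <- sim_config(seed = 9, tissues = c("liver", "lung"),
                    n_cells_per_type = 25,
                    genome = c(chr1 = 6e6, chr2 = 6e6),
                    n_housekeeping_peaks = 60, n_tissue_peaks_per_tissue = 15,
                    n_celltype_peaks_per_type = 15, lowq_cell_rate = 0,
                    doublet_rate = 0)
  ds <- simulate_dataset(cfg)
  frac <- frac_overlapping(ds$fragments, ds$truth$peaks)
  expect_lt(abs(frac - cfg$signal_fraction), 0.03)

  # background-only limit: in-peak fraction collapses to the bp fraction
  cfg0 <- sim_config(seed = 9, tissues = c("liver", "lung"),
                     n_cells_per_type = 10,
                     genome = c(chr1 = 6e6, chr2 = 6e6),
                     n_housekeeping_peaks = 60, n_tissue_peaks_per_tissue = 15,
                     n_celltype_peaks_per_type = 15, lowq_cell_rate = 0,
                     doublet_rate = 0, signal_fraction = 0)
  ds0 <- simulate_dataset(cfg0)
  frac0 <- frac_overlapping(ds0$fragments, ds0$truth$peaks)
  peak_bp <- nrow(ds0$truth$peaks) * cfg0$peak_width_bp
  expect_lt(abs(frac0 - peak_bp / sum(cfg0$genome)), 0.01)
})

test_that("per-cell fragment counts recover the lognormal law (KS)", {
  cfg <- sim_config(seed = 31, tissues = c("liver", "lung"),
                    stromal_types = c("endothelial", "fibroblast"),
                    restricted_type_per_tissue = FALSE,
                    n_cells_per_type = 250,  # 1000 cells
                    genome = c(chr1 = 8e6, chr2 = 8e6),
                    n_housekeeping_peaks = 50, n_tissue_peaks_per_tissue = 10,
                    n_celltype_peaks_per_type = 10,
                    doublet_rate = 0, lowq_cell_rate = 0,
                    motif_peaks = c(KLF = "housekeeping"))
  ds <- simulate_dataset(cfg)
  nf <- ds$fragments[, .(n = sum(count)), by = barcode]
  ks <- suppressWarnings(stats::ks.test(
    log(nf$n), "pnorm", cfg$frags_per_cell_meanlog, cfg$frags_per_cell_sdlog))
  expect_gt(ks$p.value, 0.01)
})

test_that("full footprint depletion empties motif centers in bound cells", {
  cfg <- small_sim_config(footprint_depletion = 1)
  ds <- simulate_dataset(cfg)
  count_zone <- function(frags, mz) {
    ins <- data.table::data.table(chrom = rep(frags$chrom, 2L),
                                  pos = c(frags$start, frags$end - 1L))
    tot <- 0L
    for (i in seq_len(nrow(mz))) {
      tot <- tot + nrow(ins[chrom == mz$chrom[i] &
                              abs(pos - mz$summit[i]) <= 10])
    }
    tot
  }
  # housekeeping-borne motif: open (hence bound) in every cell
  expect_identical(count_zone(ds$fragments,
                              ds$truth$peaks[motif == "KLF"]), 0L)
  # cell-type-borne motif: insertion-free in the carrier population
  mac <- ds$cells[cell_type == "macrophage", barcode]
  expect_identical(count_zone(ds$fragments[barcode %in% mac],
                              ds$truth$peaks[motif == "RUNX"]), 0L)
  # non-carriers still insert background there (depletion is state-bound)
  other <- ds$cells[cell_type != "macrophage", barcode]
  expect_gt(count_zone(ds$fragments[barcode %in% other],
                       ds$truth$peaks[motif == "RUNX"]), 0L)
})

test_that("tissue peaks are shared across cell types of the tissue", {
  # strong signal: every non-lowq liver cell should touch nearly all liver
  # tissue peaks at >= 2000 fragments/cell
  ds <- small_dataset()
  cells <- ds$cells[is_lowq == FALSE & is_doublet == FALSE & tissue == "liver"]
  pm <- make_peak_matrix(ds$fragments[barcode %in% cells$barcode],
                         ds$truth$peaks, ceiling = 1e9,
                         barcodes = cells$barcode)
  tp <- ds$truth$peaks[class == "tissue" & owner == "liver", peak_id]
  cover <- Matrix::rowSums(pm$counts[, tp, drop = FALSE] > 0) / length(tp)
  expect_gte(mean(cover >= 0.95), 0.95)
})

test_that("truth files round-trip losslessly and keep BED conventions", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_truth(ds$truth, ds$cells, dir)
  back <- read_truth(dir)
  expect_equal(back$peaks$start, ds$truth$peaks$start)
  expect_equal(back$peaks$end, ds$truth$peaks$end)
  expect_equal(back$peaks$class, ds$truth$peaks$class)
  expect_equal(back$peaks$motif, ds$truth$peaks$motif)
  expect_equal(back$genes, ds$truth$genes, ignore_attr = TRUE)
  expect_identical(back$open_peaks, ds$truth$open_peaks)
  # 0-based half-open: width is exactly end - start
  expect_true(all(back$peaks$end - back$peaks$start == ds$config$peak_width_bp))

  # empty cell table -> header-only TSV
  write_truth(ds$truth, ds$cells[0], dir)
  expect_identical(nrow(read_cells_tsv(file.path(dir, "cells.tsv"))), 0L)
})
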