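#' Simulation configuration
#'
#' Parameters of the synthetic scATAC-seq dataset. The defaults emulate the
#' structure of a multi-organ atlas: 9 tissues, three stromal cell types
#' (endothelial, fibroblast, macrophage) shared by every tissue plus one
#' organ-restricted parenchymal type per tissue, housekeeping peaks open in
#' all cells, tissue-level peaks open in every cell of one tissue regardless
#' of type, and cell-type peaks open in one type across tissues. Fragment
#' counts per cell are lognormal (median 2500); fragment lengths follow a
#' nucleosome-free / mono-nucleosome mixture; a fraction of barcodes are
#' doublets (unions of two cells' fragments) or low-quality background-only
#' cells; Tn5 insertions inside planted motif centers are depleted by
#' `footprint_depletion`.
#'
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param tissues character vector of tissue names (default 9 organs).
#' @param stromal_types cell types present in every tissue.
#' @param restricted_type_per_tissue if TRUE each tissue also gets a private
#'   `<tissue>_parenchymal` type.
#' @param n_cells_per_type cells per (tissue, type) combination.
#' @param genome named integer vector of chromosome lengths (bp).
#' @param n_housekeeping_peaks,n_tissue_peaks_per_tissue,n_celltype_peaks_per_type
#'   planted peak counts per class.
#' @param peak_width_bp planted peak width (default 500).
#' @param min_peak_separation_bp minimum gap between planted peaks, kept
#'   large enough that TSS flank windows stay in background.
#' @param signal_fraction probability a fragment is drawn from an open peak
#'   rather than uniform background (default 0.6).
#' @param frags_per_cell_meanlog,frags_per_cell_sdlog lognormal parameters of
#'   per-cell fragment counts.
#' @param fraglen_weights,fraglen_means,fraglen_sds,fraglen_range two-component
#'   normal mixture for fragment lengths, truncated to `fraglen_range`.
#' @param doublet_rate fraction of extra doublet barcodes (default 0.05).
#' @param lowq_cell_rate fraction of extra low-quality barcodes.
#' @param lowq_frag_range fragment-count range for low-quality cells; chosen
#'   so they fail both QC thresholds.
#' @param footprint_depletion multiplier `1 - footprint_depletion` applied to
#'   insertion probability within +/-10 bp of planted motif centers.
#' @param motif_peaks named character vector mapping motif name to the peak
#'   class carrying it: `"housekeeping"`, `"tissue"`, `"celltype"`, or
#'   owner-qualified `"celltype:macrophage"` / `"tissue:liver"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       tissues = c("liver", "lung", "kidney", "heart", "brain",
                                   "spleen", "intestine", "muscle", "pancreas"),
                       stromal_types = c("endothelial", "fibroblast", "macrophage"),
                       restricted_type_per_tissue = TRUE,
                       n_cells_per_type = 60L,
                       genome = c(chr1 = 12e6, chr2 = 12e6, chr3 = 12e6, chr4 = 12e6),
                       n_housekeeping_peaks = 200L,
                       n_tissue_peaks_per_tissue = 20L,
                       n_celltype_peaks_per_type = 20L,
                       peak_width_bp = 500L,
                       min_peak_separation_bp = 6000L,
                       signal_fraction = 0.6,
                       frags_per_cell_meanlog = log(2500),
                       frags_per_cell_sdlog = 0.35,
                       fraglen_weights = c(0.7, 0.3),
                       fraglen_means = c(75, 220),
                       fraglen_sds = c(15, 30),
                       fraglen_range = c(20L, 600L),
                       doublet_rate = 0.05,
                       lowq_cell_rate = 0.05,
                       lowq_frag_range = c(300L, 800L),
                       footprint_depletion = 0.5,
                       motif_peaks = c(KLF = "housekeeping",
                                       RUNX = "celltype:macrophage")) {
  cfg <- list(seed = as.integer(seed), tissues = tissues,
              stromal_types = stromal_types,
              restricted_type_per_tissue = isTRUE(restricted_type_per_tissue),
              n_cells_per_type = as.integer(n_cells_per_type),
              genome = genome,
              n_housekeeping_peaks = as.integer(n_housekeeping_peaks),
              n_tissue_peaks_per_tissue = as.integer(n_tissue_peaks_per_tissue),
              n_celltype_peaks_per_type = as.integer(n_celltype_peaks_per_type),
              peak_width_bp = as.integer(peak_width_bp),
              min_peak_separation_bp = as.integer(min_peak_separation_bp),
              signal_fraction = signal_fraction,
              frags_per_cell_meanlog = frags_per_cell_meanlog,
              frags_per_cell_sdlog = frags_per_cell_sdlog,
              fraglen_weights = fraglen_weights / sum(fraglen_weights),
              fraglen_means = fraglen_means, fraglen_sds = fraglen_sds,
              fraglen_range = as.integer(fraglen_range),
              doublet_rate = doublet_rate,
              lowq_cell_rate = lowq_cell_rate,
              lowq_frag_range = as.integer(lowq_frag_range),
              footprint_depletion = footprint_depletion,
              motif_peaks = motif_peaks)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_cells_per_type, cfg$n_housekeeping_peaks,
              cfg$peak_width_bp, cfg$genome)
  if (any(counts <= 0)) stopf("sim_config counts and lengths must be positive")
  if (cfg$n_tissue_peaks_per_tissue < 0 || cfg$n_celltype_peaks_per_type < 0) {
    stopf("peak counts must be non-negative")
  }
  rates <- c(cfg$signal_fraction, cfg$doublet_rate, cfg$lowq_cell_rate,
             cfg$footprint_depletion)
  if (any(rates < 0 | rates > 1)) {
    stopf("signal_fraction, doublet_rate, lowq_cell_rate, footprint_depletion must be in [0, 1]")
  }
  if (is.null(names(cfg$genome)) || any(!nzchar(names(cfg$genome)))) {
    stopf("genome must be a named vector of chromosome lengths")
  }
  if (min(cfg$genome) <= 2L * (cfg$peak_width_bp + cfg$min_peak_separation_bp)) {
    stopf("chromosome lengths must exceed peak placement requirements")
  }
  invisible(cfg)
}

# (tissue, cell type) combinations present in a configuration.
sim_groups <- function(config) {
  gs <- data.table::CJ(tissue = config$tissues, cell_type = config$stromal_types,
                       sorted = FALSE)
  if (config$restricted_type_per_tissue) {
    gs <- rbind(gs, data.table::data.table(
      tissue = config$tissues,
      cell_type = paste0(config$tissues, "_parenchymal")))
  }
  data.table::setorder(gs, tissue, cell_type)
  gs[, group := .I]
  gs[]
}

#' Build the planted ground truth for a simulated dataset
#'
#' Places non-overlapping fixed-width peaks of three classes (housekeeping,
#' tissue, celltype) on the genome by rejection sampling, pairs every
#' cell-type peak with a promoter gene whose TSS sits on the peak summit,
#' plants motif instances at the summits of carrier peaks, and records which
#' peaks are open in which (tissue, cell type) combination: housekeeping
#' peaks in all cells, tissue peaks in all cells of that tissue, cell-type
#' peaks in that type in every tissue where it occurs.
#'
#' @param config a [sim_config()].
#' @return a `truth_catalog`: list with `peaks` (data.table: peak_id, chrom,
#'   start, end, summit, class, owner, motif, motif_strand), `genes`
#'   (data.table: gene, chrom, strand, start, end, tss, paired_peak),
#'   `groups` (tissue x cell_type table) and `open_peaks` (per-group integer
#'   vectors of open peak row indices).
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_truth_impl(config))
}

build_truth_impl <- function(config) {
  groups <- sim_groups(config)
  types <- unique(groups$cell_type)

  classes <- c(rep("housekeeping", config$n_housekeeping_peaks),
               rep("tissue", config$n_tissue_peaks_per_tissue * length(config$tissues)),
               rep("celltype", config$n_celltype_peaks_per_type * length(types)))
  owners <- c(rep(NA_character_, config$n_housekeeping_peaks),
              rep(config$tissues, each = config$n_tissue_peaks_per_tissue),
              rep(types, each = config$n_celltype_peaks_per_type))
  n_peaks <- length(classes)

  pl <- place_peaks(n_peaks, config$genome, config$peak_width_bp,
                    config$min_peak_separation_bp)
  peaks <- data.table::data.table(
    chrom = pl$chrom, start = pl$start, end = pl$start + config$peak_width_bp,
    class = classes, owner = owners)
  peaks[, summit := start + config$peak_width_bp %/% 2L]
  # shuffle placement/class pairing so no class is confined to one region
  peaks <- peaks[sample.int(n_peaks)]
  data.table::setorder(peaks, chrom, start)
  peaks[, peak_id := sprintf("%s:%d-%d", chrom, start, end)]

  peaks[, motif := NA_character_]
  peaks[, motif_strand := NA_character_]
  for (m in names(config$motif_peaks)) {
    spec <- strsplit(config$motif_peaks[[m]], ":", fixed = TRUE)[[1]]
    sel <- peaks$class == spec[1] & is.na(peaks$motif)
    if (length(spec) > 1L) sel <- sel & !is.na(peaks$owner) & peaks$owner == spec[2]
    if (!any(sel)) stopf("motif '%s' maps to class '%s' with no peaks",
                         m, config$motif_peaks[[m]])
    peaks[sel, motif := m]
    peaks[sel, motif_strand := sample(c("+", "-"), sum(sel), replace = TRUE)]
  }

  # promoter genes: every cell-type peak is a marker gene's promoter (TSS on
  # the summit), and every housekeeping peak a housekeeping gene's promoter —
  # the latter carry the TSS-enrichment signal shared by all cells, as in
  # real data where QC enrichment rests on ubiquitously active promoters
  ct <- which(peaks$class %in% c("celltype", "housekeeping"))
  genes <- if (length(ct)) {
    strand <- sample(c("+", "-"), length(ct), replace = TRUE)
    len <- round(runif(length(ct), 2000, 8000))
    tss <- peaks$summit[ct]
    gstart <- ifelse(strand == "+", tss, pmax(0, tss + 1 - len))
    gend <- ifelse(strand == "+",
                   pmin(tss + len, config$genome[peaks$chrom[ct]]), tss + 1)
    owner <- data.table::fifelse(peaks$class[ct] == "housekeeping", "hk",
                                 peaks$owner[ct])
    data.table::data.table(
      gene = paste0(owner, "_g",
                    stats::ave(seq_along(ct), owner, FUN = seq_along)),
      class = peaks$class[ct],
      chrom = peaks$chrom[ct], strand = strand,
      start = as.integer(gstart), end = as.integer(gend),
      tss = as.integer(tss), paired_peak = peaks$peak_id[ct])
  } else {
    data.table::data.table(gene = character(), class = character(),
                           chrom = character(),
                           strand = character(), start = integer(),
                           end = integer(), tss = integer(),
                           paired_peak = character())
  }

  open_peaks <- lapply(seq_len(nrow(groups)), function(g) {
    ti <- groups$tissue[g]; ty <- groups$cell_type[g]
    which(peaks$class == "housekeeping" |
            (peaks$class == "tissue" & peaks$owner == ti) |
            (peaks$class == "celltype" & peaks$owner == ty))
  })

  structure(list(peaks = peaks, genes = genes, groups = groups,
                 open_peaks = open_peaks, config = config),
            class = "truth_catalog")
}

# Rejection-sample n non-overlapping peak starts with a minimum pairwise gap.
place_peaks <- function(n, genome, width, min_sep, max_rounds = 200L) {
  margin <- min_sep + width
  chroms <- names(genome)
  kept_chrom <- character(0); kept_start <- integer(0)
  need <- n
  for (round in seq_len(max_rounds)) {
    if (need <= 0L) break
    m <- max(need * 2L, 10L)
    ch <- sample(chroms, m, replace = TRUE, prob = as.numeric(genome))
    st <- as.integer(floor(runif(m, margin, genome[ch] - margin)))
    cand_chrom <- c(kept_chrom, ch)
    cand_start <- c(kept_start, st)
    keep_flag <- logical(length(cand_start))
    keep_flag[seq_along(kept_start)] <- TRUE
    o <- order(cand_chrom, cand_start)
    last_chrom <- ""; last_start <- -Inf
    for (i in o) {
      if (keep_flag[i]) {
        last_chrom <- cand_chrom[i]; last_start <- cand_start[i]
        next
      }
      if (sum(keep_flag) - length(kept_start) >= need) next
      if (cand_chrom[i] != last_chrom ||
          cand_start[i] - last_start >= width + min_sep) {
        # new candidate must also clear the next already-kept peak
        keep_flag[i] <- TRUE
        last_chrom <- cand_chrom[i]; last_start <- cand_start[i]
      }
    }
    kept_chrom <- cand_chrom[keep_flag]
    kept_start <- cand_start[keep_flag]
    # re-check pairwise separation after merging (drop violators)
    o <- order(kept_chrom, kept_start)
    kept_chrom <- kept_chrom[o]; kept_start <- kept_start[o]
    ok <- c(TRUE, kept_chrom[-1] != kept_chrom[-length(kept_chrom)] |
              diff(kept_start) >= width + min_sep)
    kept_chrom <- kept_chrom[ok]; kept_start <- kept_start[ok]
    need <- n - length(kept_chrom)
  }
  if (need > 0L) {
    stopf(paste0("could not place %d peaks of width %d with separation %d on a ",
                 "%.0f bp genome after %d rounds; enlarge the genome or reduce ",
                 "peak counts"), n, width, min_sep, sum(genome), max_rounds)
  }
  idx <- sample.int(length(kept_chrom), n)
  list(chrom = kept_chrom[idx], start = kept_start[idx])
}

#' Simulate a fragment file from a truth catalog
#'
#' Draws per-cell fragment counts from the configured lognormal, assigns each
#' fragment with probability `signal_fraction` to a peak open for the cell's
#' (tissue, type) combination — uniformly among open peaks, centered on the
#' summit with Gaussian jitter, lengths from the nucleosome mixture — and
#' otherwise to uniform genomic background. Insertions (fragment start and
#' end - 1) falling within +/-10 bp of a planted motif center are accepted
#' with probability `1 - footprint_depletion` (rejected fragments are
#' redrawn). Low-quality barcodes draw only background fragments; doublet
#' barcodes receive the union of two distinct cells' fragments. Fragments
#' extending past a chromosome end are resampled, never emitted.
#'
#' @param catalog a [build_truth()] result.
#' @param config the same [sim_config()].
#' @return list with `fragments` (data.table: chrom, start, end, barcode,
#'   count; sorted by chrom then start) and `cells` (data.table: barcode,
#'   tissue, cell_type, is_doublet, partner_1, partner_2, is_lowq,
#'   target_fragments).
#' @export
simulate_fragments <- function(catalog, config) {
  stopifnot(inherits(catalog, "truth_catalog"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, simulate_fragments_impl(catalog, config))
}

simulate_fragments_impl <- function(catalog, config) {
  groups <- catalog$groups
  genome <- config$genome
  chroms <- names(genome)
  offsets <- c(0, cumsum(as.numeric(genome)))
  names(offsets) <- c(chroms, "END")

  # singlet cells
  sing <- groups[rep(seq_len(nrow(groups)), each = config$n_cells_per_type)]
  n_sing <- nrow(sing)
  sing[, barcode := sprintf("BC%05d", seq_len(n_sing))]
  sing[, is_doublet := FALSE]
  sing[, is_lowq := FALSE]
  sing[, target_fragments := pmax(50L, as.integer(round(rlnorm(
    n_sing, config$frags_per_cell_meanlog, config$frags_per_cell_sdlog))))]

  # low-quality cells: background-only, shallow
  n_lowq <- round(config$lowq_cell_rate * n_sing)
  if (n_lowq > 0) {
    gl <- sample.int(nrow(groups), n_lowq, replace = TRUE)
    lowq <- groups[gl]
    lowq[, barcode := sprintf("LQ%05d", seq_len(n_lowq))]
    lowq[, is_doublet := FALSE]
    lowq[, is_lowq := TRUE]
    lowq[, target_fragments := sample(
      config$lowq_frag_range[1]:config$lowq_frag_range[2], n_lowq, replace = TRUE)]
  } else lowq <- NULL

  cells <- rbind(sing, lowq)
  cells[, partner_1 := NA_character_]
  cells[, partner_2 := NA_character_]

  # fragment slots for singlets + lowq
  n_frag <- cells$target_fragments
  cell_idx <- rep(seq_len(nrow(cells)), n_frag)
  total <- length(cell_idx)
  is_signal <- runif(total) < config$signal_fraction & !cells$is_lowq[cell_idx]

  # per-group concatenated open-peak index vectors for uniform sampling
  open_len <- lengths(catalog$open_peaks)
  open_concat <- unlist(catalog$open_peaks, use.names = FALSE)
  open_off <- c(0L, cumsum(open_len))
  grp_of_frag <- cells$group[cell_idx]

  peaks <- catalog$peaks
  pk_chrom <- peaks$chrom; pk_summit <- peaks$summit
  half_w <- config$peak_width_bp / 2

  # motif depletion zones (global genome coordinates, disjoint); depletion
  # applies per cell state: insertions are lost only where the motif's peak
  # is open in that cell's (tissue, type), i.e. where the factor is bound
  mz_idx <- which(!is.na(peaks$motif))
  have_zones <- length(mz_idx) > 0 && config$footprint_depletion > 0
  if (have_zones) {
    zs <- offsets[peaks$chrom[mz_idx]] + peaks$summit[mz_idx] - 10
    ze <- offsets[peaks$chrom[mz_idx]] + peaks$summit[mz_idx] + 10
    o <- order(zs); zs <- zs[o]; ze <- ze[o]
    zone_peak <- mz_idx[o]
    open_mat <- matrix(FALSE, nrow(groups), nrow(peaks))
    for (g in seq_len(nrow(groups))) {
      open_mat[g, catalog$open_peaks[[g]]] <- TRUE
    }
  }
  # returns the planted-motif peak whose central zone covers pos, else 0
  zone_of <- function(chrom, pos) {
    g <- offsets[chrom] + pos
    i <- findInterval(g, zs)
    hit <- i > 0 & g <= ze[pmax(i, 1L)]
    ifelse(hit, zone_peak[pmax(i, 1L)], 0L)
  }

  draw_len <- function(n) {
    comp <- runif(n) < config$fraglen_weights[1]
    len <- round(ifelse(comp,
                        rnorm(n, config$fraglen_means[1], config$fraglen_sds[1]),
                        rnorm(n, config$fraglen_means[2], config$fraglen_sds[2])))
    as.integer(pmin(pmax(len, config$fraglen_range[1]), config$fraglen_range[2]))
  }

  f_chrom <- character(total); f_start <- integer(total); f_end <- integer(total)
  need <- seq_len(total)
  accept_p <- 1 - config$footprint_depletion
  iter <- 0L
  while (length(need) > 0L) {
    iter <- iter + 1L
    if (iter > 200L) stopf("fragment resampling did not terminate")
    n <- length(need)
    sig <- is_signal[need]
    ch <- character(n); st <- integer(n); len <- draw_len(n)

    if (any(sig)) {
      g <- grp_of_frag[need[sig]]
      r <- 1L + as.integer(floor(runif(sum(sig)) * open_len[g]))
      pk <- open_concat[open_off[g] + r]
      # midpoint uniform over summit +/- (half-width + len/2): every fragment
      # overlaps its peak and the per-bp insertion density is flat across the
      # full peak width (so footprint flank normalization is unbiased)
      spread <- half_w + len[sig] / 2
      mid <- pk_summit[pk] + runif(sum(sig), -spread, spread)
      ch[sig] <- pk_chrom[pk]
      st[sig] <- as.integer(round(mid)) - len[sig] %/% 2L
    }
    if (any(!sig)) {
      m <- sum(!sig)
      gp <- floor(runif(m) * sum(as.numeric(genome)))
      ci <- findInterval(gp, offsets[seq_along(chroms)], rightmost.closed = FALSE)
      ch[!sig] <- chroms[ci]
      st[!sig] <- as.integer(gp - offsets[ci])
    }
    en <- st + len
    ok <- st >= 0L & en <= genome[ch] & en > st
    if (have_zones && any(ok)) {
      grp <- grp_of_frag[need[ok]]
      z1 <- zone_of(ch[ok], st[ok])
      z2 <- zone_of(ch[ok], en[ok] - 1L)
      k <- (z1 > 0 & open_mat[cbind(grp, pmax(z1, 1L))]) +
        (z2 > 0 & open_mat[cbind(grp, pmax(z2, 1L))])
      keep <- runif(sum(ok)) < accept_p^k
      ok[ok] <- keep
    }
    fill <- need[ok]
    f_chrom[fill] <- ch[ok]; f_start[fill] <- st[ok]; f_end[fill] <- en[ok]
    need <- need[!ok]
  }

  frags <- data.table::data.table(
    chrom = f_chrom, start = f_start, end = f_end,
    barcode = cells$barcode[cell_idx], count = 1L)

  # doublets: union of two distinct singlet cells' fragments
  n_doub <- round(config$doublet_rate * n_sing)
  if (n_doub > 0) {
    pairs <- t(vapply(seq_len(n_doub), function(i) sample.int(n_sing, 2L),
                      integer(2)))
    db_bc <- sprintf("DB%05d", seq_len(n_doub))
    p1 <- sing$barcode[pairs[, 1]]; p2 <- sing$barcode[pairs[, 2]]
    dsrc <- data.table::data.table(barcode = c(p1, p2),
                                   new_bc = rep(db_bc, 2L))
    dfr <- merge(frags, dsrc, by = "barcode", allow.cartesian = TRUE)
    dfr <- dfr[, .(chrom, start, end, barcode = new_bc, count)]
    frags <- rbind(frags, dfr)
    dcells <- data.table::data.table(
      tissue = sing$tissue[pairs[, 1]], cell_type = sing$cell_type[pairs[, 1]],
      group = sing$group[pairs[, 1]], barcode = db_bc, is_doublet = TRUE,
      is_lowq = FALSE,
      target_fragments = sing$target_fragments[pairs[, 1]] +
        sing$target_fragments[pairs[, 2]],
      partner_1 = p1, partner_2 = p2)
    cells <- rbind(cells, dcells, use.names = TRUE)
  }

  frags[, chrom_i := match(chrom, chroms)]
  data.table::setorder(frags, chrom_i, start)
  frags[, chrom_i := NULL]
  data.table::setcolorder(cells, c("barcode", "tissue", "cell_type", "group",
                                   "is_doublet", "partner_1", "partner_2",
                                   "is_lowq", "target_fragments"))
  list(fragments = frags[], cells = cells[])
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [build_truth()] then [simulate_fragments()].
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `fragments`, `cells`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- build_truth(config)
  sim <- simulate_fragments(truth, config)
  list(truth = truth, fragments = sim$fragments, cells = sim$cells)
}

#' Write ground-truth tables to disk
#'
#' Emits `peaks.bed` (0-based half-open BED with class/owner/motif columns),
#' `genes.tsv`, and `cells.tsv` under `out_dir`. The files round-trip through
#' [read_peaks_bed()], [read_genes_tsv()] and [read_cells_tsv()] losslessly.
#'
#' @param catalog a `truth_catalog`.
#' @param cells the cell-truth table from [simulate_fragments()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_truth <- function(catalog, cells, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peaks = file.path(out_dir, "peaks.bed"),
             genes = file.path(out_dir, "genes.tsv"),
             cells = file.path(out_dir, "cells.tsv"))
  pk <- catalog$peaks[, .(chrom, start, end, class,
                          owner = data.table::fifelse(is.na(owner), ".", owner),
                          motif = data.table::fifelse(is.na(motif), ".", motif),
                          motif_strand = data.table::fifelse(
                            is.na(motif_strand), ".", motif_strand))]
  data.table::fwrite(pk, paths["peaks"], sep = "\t", col.names = FALSE)
  data.table::fwrite(catalog$genes, paths["genes"], sep = "\t")
  data.table::fwrite(cells, paths["cells"], sep = "\t")
  invisible(paths)
}
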