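#' Build a genome-wide tile matrix
#'
#' Counts Tn5 insertion sites (both fragment ends, count-weighted) per
#' barcode in fixed non-overlapping genomic bins of `tile_bp` (default 5 kb).
#' Tiles are indexed genome-wide in chromosome order; the last partial tile
#' of each chromosome is included.
#'
#' @param fragments fragment data.table.
#' @param genome named vector of chromosome lengths.
#' @param tile_bp bin size in bp.
#' @param barcodes optional barcode universe for the rows (defaults to the
#'   barcodes present); barcodes without fragments get empty rows.
#' @return a tile-flavor [feature_matrix()].
#' @export
make_tile_matrix <- function(fragments, genome, tile_bp = 5000L,
                             barcodes = NULL) {
  bad <- setdiff(unique(fragments$chrom), names(genome))
  if (length(bad)) stopf("fragment chromosome(s) not in genome: %s",
                         paste(bad, collapse = ", "))
  tile_bp <- as.integer(tile_bp)
  n_tiles <- stats::setNames(pmax(1L, as.integer(ceiling(genome / tile_bp))),
                             names(genome))
  tile_off <- stats::setNames(c(0L, cumsum(n_tiles)), c(names(genome), ""))
  labels <- unlist(lapply(names(genome), function(ch) {
    k <- seq_len(n_tiles[ch]) - 1L
    sprintf("%s:%d-%d", ch, k * tile_bp,
            pmin((k + 1L) * tile_bp, as.integer(genome[ch])))
  }), use.names = FALSE)
  barcodes <- barcodes %||% sort(unique(fragments$barcode))

  pos <- c(fragments$start, fragments$end - 1L)
  chrom <- rep(fragments$chrom, 2L)
  w <- rep(fragments$count, 2L)
  bc <- match(rep(fragments$barcode, 2L), barcodes)
  if (anyNA(bc)) stopf("fragments contain barcodes outside the given universe")
  tile <- tile_off[chrom] + pos %/% tile_bp + 1L

  m <- Matrix::sparseMatrix(i = bc, j = tile, x = w,
                            dims = c(length(barcodes), length(labels)),
                            dimnames = list(barcodes, labels))
  feature_matrix(m, flavor = "tile")
}

#' Call peaks from pseudobulk insertion pileups
#'
#' A minimal self-contained caller: per group, insertion counts are piled up
#' per base pair; candidate summits are positions whose count exceeds the
#' Poisson upper-tail threshold at `p_cutoff` against the genome-wide mean
#' insertion rate; candidates (pooled across groups) are accepted greedily by
#' descending count, skipping any within `width` of an accepted summit; each
#' accepted summit becomes a `width`-bp interval centered on it.
#'
#' @param fragments fragment data.table.
#' @param groups optional vector or list mapping barcodes to group labels; a
#'   named vector `groups[barcode] = label`. NULL treats all fragments as one
#'   group.
#' @param genome named vector of chromosome lengths.
#' @param width emitted peak width (default 500).
#' @param p_cutoff Poisson tail probability for candidate summits.
#' @return data.table (chrom, start, end, summit, score, peak_id), sorted,
#'   non-overlapping.
#' @export
call_peaks_pseudobulk <- function(fragments, genome, groups = NULL,
                                  width = 500L, p_cutoff = 1e-4) {
  if (nrow(fragments) == 0) stopf("empty fragment set")
  width <- as.integer(width)
  glab <- if (is.null(groups)) rep("all", nrow(fragments)) else {
    unname(groups[fragments$barcode])
  }
  genome_bp <- sum(as.numeric(genome))
  cand <- data.table::rbindlist(lapply(split(seq_len(nrow(fragments)), glab),
                                       function(ridx) {
    fr <- fragments[ridx]
    ins <- data.table::data.table(chrom = rep(fr$chrom, 2L),
                                  pos = c(fr$start, fr$end - 1L),
                                  w = rep(fr$count, 2L))
    pile <- ins[, .(n = sum(w)), by = .(chrom, pos)]
    lambda <- sum(ins$w) / genome_bp
    # minimal count whose upper tail P(X >= c) <= p_cutoff
    cmin <- stats::qpois(p_cutoff, lambda, lower.tail = FALSE) + 1L
    pile[n >= cmin]
  }))
  if (nrow(cand) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), summit = integer(),
                                  score = numeric(), peak_id = character()))
  }
  cand <- cand[, .(n = max(n)), by = .(chrom, pos)]
  data.table::setorder(cand, -n, chrom, pos)
  # greedy exclusion: accept by descending count, skip within `width` of an
  # accepted summit on the same chromosome
  acc <- greedy_summits(cand$chrom, cand$pos, width)
  peaks <- cand[acc]
  half <- width %/% 2L
  out <- data.table::data.table(chrom = peaks$chrom,
                                start = peaks$pos - half,
                                end = peaks$pos - half + width,
                                summit = peaks$pos, score = as.numeric(peaks$n))
  out <- out[start >= 0 & end <= genome[chrom]]
  data.table::setorder(out, chrom, start)
  out[, peak_id := sprintf("%s:%d-%d", chrom, start, end)]
  out[]
}

greedy_summits <- function(chrom, pos, width) {
  keep <- logical(length(pos))
  by_chrom <- split(seq_along(pos), chrom)
  for (idx in by_chrom) {
    accepted <- integer(0)
    for (i in idx) {  # idx already in descending-count order
      if (!length(accepted) || all(abs(pos[accepted] - pos[i]) >= width)) {
        keep[i] <- TRUE
        accepted <- c(accepted, i)
      }
    }
  }
  which(keep)
}

#' Build the capped peak matrix
#'
#' Counts insertions per barcode in each (non-overlapping) peak and caps
#' every entry at `ceiling` to blunt outliers. The cached row depth is the
#' uncapped total insertion count per barcode, so depth normalization is
#' unaffected by the cap.
#'
#' @param fragments fragment data.table.
#' @param peaks peak table with chrom, start, end (0-based half-open) and
#'   peak_id.
#' @param ceiling per-entry cap (default 4).
#' @param barcodes optional row universe.
#' @return a peak-flavor [feature_matrix()].
#' @export
make_peak_matrix <- function(fragments, peaks, ceiling = 4L, barcodes = NULL) {
  pk <- data.table::as.data.table(peaks)[order(chrom, start)]
  if (nrow(pk) > 1L) {
    same <- pk$chrom[-1] == pk$chrom[-nrow(pk)]
    if (any(same & pk$start[-1] < pk$end[-nrow(pk)])) {
      stopf("overlapping peaks are not allowed in a peak matrix")
    }
  }
  barcodes <- barcodes %||% sort(unique(fragments$barcode))
  if (!"peak_id" %in% names(pk)) {
    pk[, peak_id := sprintf("%s:%d-%d", chrom, start, end)]
  }

  # unrolled genome coordinates; peaks are disjoint so findInterval suffices
  chroms <- unique(c(pk$chrom, fragments$chrom))
  span <- vapply(chroms, function(ch)
    max(c(pk[chrom == ch, end], fragments[chrom == ch, end], 0L)) + 1, 0)
  offs <- stats::setNames(c(0, cumsum(span)), c(chroms, ""))
  gstart <- offs[pk$chrom] + pk$start
  gend <- offs[pk$chrom] + pk$end
  o <- order(gstart)
  gstart <- gstart[o]; gend <- gend[o]; pids <- pk$peak_id[o]

  gpos <- c(offs[fragments$chrom] + fragments$start,
            offs[fragments$chrom] + fragments$end - 1L)
  bc <- match(rep(fragments$barcode, 2L), barcodes)
  if (anyNA(bc)) stopf("fragments contain barcodes outside the given universe")
  w <- rep(fragments$count, 2L)
  pi <- findInterval(gpos, gstart)
  hit <- pi > 0 & gpos < gend[pmax(pi, 1L)]

  depth <- Matrix::rowSums(Matrix::sparseMatrix(
    i = bc, j = rep(1L, length(bc)), x = w,
    dims = c(length(barcodes), 1L)))
  m <- Matrix::sparseMatrix(i = bc[hit], j = pi[hit], x = w[hit],
                            dims = c(length(barcodes), length(pids)),
                            dimnames = list(barcodes, pids))
  m@x <- pmin(m@x, as.numeric(ceiling))
  feature_matrix(m, flavor = "peak", depth = depth)
}
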