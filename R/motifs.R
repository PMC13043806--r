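#' Motif hits by PWM scanning or from planted coordinates
#'
#' Two modes. Sequence mode: `x` is a named character vector of peak
#' sequences; each position on both strands is scored by the log-odds of the
#' PWM against its background, and positions scoring at least
#' `threshold_frac` of the maximum achievable score are hits. Planted mode:
#' `x` is a peak table carrying `motif` / `motif_strand` columns (the
#' simulator's truth), and hits are simply the planted instances of this
#' PWM's motif — no sequence needed.
#'
#' @param x named character vector of sequences, or a peak data.table with
#'   chrom, start, end, summit, motif, motif_strand.
#' @param pwm a [pwm()] object.
#' @param threshold_frac fraction of the maximum log-odds score required
#'   (default 0.8).
#' @return data.table (motif, peak_id, offset, strand, score, chrom, center)
#'   — chrom/center only in planted mode.
#' @export
scan_pwm <- function(x, pwm, threshold_frac = 0.8) {
  if (!inherits(pwm, "pwm")) stopf("pwm must be a pwm object")
  name <- attr(pwm, "name")
  if (is.data.frame(x)) {
    pk <- data.table::as.data.table(x)
    hits <- pk[!is.na(motif) & motif == name]
    L <- ncol(pwm)
    return(data.table::data.table(
      motif = name, peak_id = hits$peak_id,
      offset = hits$summit - hits$start - L %/% 2L,
      strand = hits$motif_strand, score = max_pwm_score(pwm),
      chrom = hits$chrom, center = hits$summit))
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  bg <- attr(pwm, "background")
  lo <- log(pmax(unclass(pwm), 1e-8) / bg)
  smax <- max_pwm_score(pwm)
  thr <- threshold_frac * smax
  L <- ncol(lo)
  out <- list()
  for (s in seq_along(x)) {
    codes <- match(strsplit(toupper(x[[s]]), "")[[1]], c("A", "C", "G", "T"))
    n <- length(codes)
    if (n < L) next
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") lo else lo[4:1, L:1, drop = FALSE]
      sc <- vapply(seq_len(n - L + 1L), function(o) {
        idx <- codes[o:(o + L - 1L)]
        if (anyNA(idx)) return(-Inf)
        sum(mat[cbind(idx, seq_len(L))])
      }, 0)
      hit <- which(sc >= thr)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          motif = name, peak_id = names(x)[s], offset = hit - 1L,
          strand = strand, score = sc[hit])
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(motif = character(), peak_id = character(),
                                  offset = integer(), strand = character(),
                                  score = numeric()))
  }
  data.table::rbindlist(out)
}

max_pwm_score <- function(pwm) {
  bg <- attr(pwm, "background")
  lo <- log(pmax(unclass(pwm), 1e-8) / bg)
  sum(apply(lo, 2L, max))
}

#' Hypergeometric motif enrichment in marker peaks
#'
#' For each motif, counts peaks carrying at least one hit among the marker
#' set and the full peak universe, computes the hypergeometric upper-tail
#' probability of drawing that many carriers in `|marker|` draws, the log2
#' fold enrichment of carrier fractions, and BH FDR across motifs. A motif
#' passes at `fdr <= 0.1` and `log2fc >= 0.1`. Motifs absent from the
#' universe are excluded (fold change undefined) with a message.
#'
#' @param hits data.table from [scan_pwm()] (any number of motifs).
#' @param marker_peaks character vector of marker peak ids (subset of
#'   `all_peaks`).
#' @param all_peaks character vector: the peak universe.
#' @param fdr,log2fc pass cutoffs (defaults 0.1 and 0.1).
#' @return data.table (motif, n_marker_with, n_all_with, log2fc, p, fdr,
#'   passes).
#' @export
motif_enrichment <- function(hits, marker_peaks, all_peaks, fdr = 0.1,
                             log2fc = 0.1) {
  if (!length(marker_peaks)) stopf("empty marker set")
  if (length(setdiff(marker_peaks, all_peaks))) {
    stopf("marker peaks must be a subset of the peak universe")
  }
  N <- length(all_peaks)
  n <- length(marker_peaks)
  motifs <- sort(unique(hits$motif))
  rows <- list()
  for (m in motifs) {
    carriers <- unique(hits[motif == m & peak_id %in% all_peaks, peak_id])
    K <- length(carriers)
    if (K == 0L) {
      message(sprintf("motif %s has no hits in the peak universe; excluded", m))
      next
    }
    k <- length(intersect(carriers, marker_peaks))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    l2 <- log2((k / n) / (K / N))
    rows[[m]] <- data.table::data.table(motif = m, n_marker_with = k,
                                        n_all_with = K, log2fc = l2, p = p)
  }
  if (!length(rows)) {
    return(data.table::data.table(motif = character(), n_marker_with = integer(),
                                  n_all_with = integer(), log2fc = numeric(),
                                  p = numeric(), fdr = numeric(),
                                  passes = logical()))
  }
  out <- data.table::rbindlist(rows)
  out[, fdr := bh_fdr(p)]
  out[, passes := fdr <= ..fdr & is.finite(log2fc) & log2fc >= ..log2fc]
  out[]
}

#' Aggregate Tn5 insertion footprint around motif hits
#'
#' Tallies insertion counts at each strand-oriented position within
#' `flank` bp of every hit center, per cell group, and normalizes each
#' group's profile by its mean count over the outer band
#' `|pos| in [norm_band[1], norm_band[2]]` (flank sum floored at 1 to guard
#' division by zero). A flat insertion field normalizes to ~1 everywhere; a
#' bound factor shows a central dip whose depth recovers the generative
#' insertion-depletion factor.
#'
#' @param fragments fragment data.table.
#' @param hits data.table with chrom, center, strand (one motif).
#' @param groups named vector mapping barcode to group label; barcodes
#'   absent from `groups` are ignored. NULL pools everything as "all".
#' @param flank half-window (default 250).
#' @param norm_band two integers, the normalization band (default c(200, 250)).
#' @return data.table (group, rel, count, normalized).
#' @export
footprint <- function(fragments, hits, groups = NULL, flank = 250L,
                      norm_band = c(200L, 250L)) {
  if (nrow(hits) == 0) stopf("no motif hits supplied")
  fr <- fragments
  if (!is.null(groups)) {
    fr <- fr[barcode %in% names(groups)]
  }
  if (nrow(fr) == 0) stopf("no fragments in any hit window")
  chroms <- unique(c(fr$chrom, hits$chrom))
  span <- vapply(chroms, function(ch)
    max(c(fr[chrom == ch, end], hits[chrom == ch, center], 0L)), 0)
  offs <- stats::setNames(c(0, cumsum(span + 2 * flank + 10)), c(chroms, ""))
  gc <- offs[hits$chrom] + hits$center
  o <- order(gc); gc <- gc[o]; hstrand <- hits$strand[o]

  ins <- data.table::data.table(
    g = c(offs[fr$chrom] + fr$start, offs[fr$chrom] + fr$end - 1L),
    barcode = rep(fr$barcode, 2L), w = rep(fr$count, 2L))
  i0 <- findInterval(ins$g, gc)
  lo <- pmax(i0, 1L); hi <- pmin(i0 + 1L, length(gc))
  use_hi <- abs(ins$g - gc[hi]) < abs(ins$g - gc[lo]) | i0 == 0L
  idx <- ifelse(use_hi, hi, lo)
  rel <- ins$g - gc[idx]
  keep <- abs(rel) <= flank
  if (!any(keep)) stopf("no fragments in any hit window")
  dt <- data.table::data.table(
    rel = as.integer(ifelse(hstrand[idx[keep]] == "-", -rel[keep], rel[keep])),
    barcode = ins$barcode[keep], w = ins$w[keep])
  dt[, group := if (is.null(groups)) "all" else unname(groups[barcode])]

  grid <- data.table::CJ(group = sort(unique(dt$group)),
                         rel = seq(-flank, flank))
  agg <- dt[, .(count = sum(w)), by = .(group, rel)]
  prof <- merge(grid, agg, by = c("group", "rel"), all.x = TRUE)
  prof[is.na(count), count := 0]
  band <- abs(prof$rel) >= norm_band[1] & abs(prof$rel) <= norm_band[2]
  prof[, normalized := {
    s <- sum(count[band[.I]])
    nb <- sum(band[.I])
    count / (max(s, 1) / nb)
  }, by = group]
  prof[]
}
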