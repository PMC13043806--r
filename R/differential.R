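#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test between two samples: exact enumeration when
#' `n_x + n_y <= 12` and there are no ties, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `statistic` (the Mann-Whitney W for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stopf("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Marker features by group-vs-rest Wilcoxon tests
#'
#' For every group and feature, tests the group's cells against all other
#' cells with the rank-sum test (normal approximation with tie and
#' continuity correction — group sizes here are far beyond the exact-test
#' regime), computes `log2fc = log2((mean_in + pc) / (mean_out + pc))` with
#' pseudocount `pc`, adjusts p-values by Benjamini-Hochberg within each group
#' across features, and flags features passing both cutoffs.
#'
#' @param matrix a [feature_matrix()] (peak or gene_score flavor).
#' @param groups vector of group labels aligned with rows.
#' @param fdr,log2fc pass cutoffs (peak defaults: 0.1 and 0.5).
#' @param pseudocount fold-change pseudocount (default 0.1).
#' @return a `MarkerTable` data.table: group, feature, mean_in, mean_out,
#'   log2fc, p_value, fdr, passes.
#' @export
marker_features <- function(matrix, groups, fdr = 0.1, log2fc = 0.5,
                            pseudocount = 0.1) {
  counts <- if (inherits(matrix, "feature_matrix")) matrix$counts else matrix
  groups <- as.character(groups)
  if (length(groups) != nrow(counts)) stopf("groups must align with matrix rows")
  glev <- sort(unique(groups))
  if (length(glev) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) == 0)) stopf("empty group")
  n <- nrow(counts)
  dense <- as.matrix(counts)
  res <- vector("list", length(glev))
  for (gi in seq_along(glev)) {
    g <- glev[gi]
    ing <- groups == g
    n1 <- sum(ing); n2 <- n - n1
    stat <- rank_sum_stats(dense, ing)
    mean_in <- colMeans(dense[ing, , drop = FALSE])
    mean_out <- colMeans(dense[!ing, , drop = FALSE])
    l2 <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
    q <- bh_fdr(stat$p)
    res[[gi]] <- data.table::data.table(
      group = g, feature = colnames(dense), mean_in = mean_in,
      mean_out = mean_out, log2fc = l2, p_value = stat$p, fdr = q,
      passes = q <= fdr & l2 >= log2fc)
  }
  data.table::rbindlist(res)
}

# Vectorized two-sided rank-sum p-values (normal approximation, tie and
# continuity corrected) for one group against the rest, per column.
rank_sum_stats <- function(dense, ing) {
  n <- nrow(dense)
  n1 <- sum(ing); n2 <- n - n1
  p <- numeric(ncol(dense))
  for (j in seq_len(ncol(dense))) {
    r <- rank(dense[, j])
    W <- sum(r[ing]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    t <- table(dense[, j])
    tie_term <- sum(t^3 - t)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p)
}
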