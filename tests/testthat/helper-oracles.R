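# Independent brute-force oracles used to freeze expected values.

# Exact two-sided Wilcoxon rank-sum p by enumeration of all splits.
oracle_wilcoxon_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(v), n1)
  stats <- apply(splits, 2L, function(idx) sum(r[idx]))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Exact hypergeometric upper tail P(X >= k) via explicit combinatorial sums.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Set-based Jaccard via plain loops.
oracle_jaccard <- function(sets) {
  m <- length(sets)
  J <- matrix(0, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    u <- union(sets[[i]], sets[[j]])
    J[i, j] <- if (length(u) == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / length(u)
  }
  J
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Fraction of fragments overlapping any peak (peaks disjoint).
frac_overlapping <- function(fragments, peaks) {
  chroms <- unique(c(fragments$chrom, peaks$chrom))
  span <- vapply(chroms, function(ch)
    max(c(fragments[chrom == ch, end], peaks[chrom == ch, end])) + 10, 0)
  offs <- stats::setNames(c(0, cumsum(span)), c(chroms, ""))
  pk <- peaks[order(offs[chrom] + start)]
  gs <- offs[pk$chrom] + pk$start
  ge <- offs[pk$chrom] + pk$end
  fs <- offs[fragments$chrom] + fragments$start
  fe <- offs[fragments$chrom] + fragments$end
  i <- findInterval(fe - 1, gs)
  mean(i > 0 & fs < ge[pmax(i, 1)])
}
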