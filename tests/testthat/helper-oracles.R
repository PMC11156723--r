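# Independent oracles used across tests. These deliberately re-derive the
# quantities by brute force (full enumeration, direct formulas) rather
# than calling the package's own code paths.

# All partitions of `values` into groups of the given sizes, as group
# label assignments; returns the exact permutation p-value of a statistic
# P(stat(perm) >= stat(observed)).
exact_perm_pvalue <- function(values, sizes, stat, observed) {
  n <- length(values)
  stopifnot(sum(sizes) == n)
  idx_all <- seq_len(n)
  count <- 0L; total <- 0L
  recurse <- function(remaining, assigned) {
    if (length(assigned) == length(sizes) - 1) {
      labels <- integer(n)
      for (g in seq_along(assigned)) labels[assigned[[g]]] <- g
      labels[remaining] <- length(sizes)
      s <- stat(values, labels)
      total <<- total + 1L
      if (s >= observed - 1e-12) count <<- count + 1L
      return(invisible())
    }
    g <- length(assigned) + 1
    combs <- utils::combn(remaining, sizes[g])
    # fix the smallest remaining index into this group only when group
    # sizes are equal and labels interchangeable? Group labels matter for
    # the statistic only through the partition, but enumerate all labelled
    # assignments: correct and simple.
    for (j in seq_len(ncol(combs)))
      recurse(setdiff(remaining, combs[, j]), c(assigned, list(combs[, j])))
  }
  recurse(idx_all, list())
  count / total
}

# Kruskal-Wallis H computed independently (direct formula on ranks).
oracle_kw_h <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  rs <- tapply(r, labels, sum)
  ns <- tapply(r, labels, length)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H / corr else 0
}

# Exact two-sided Wilcoxon p by full enumeration of all C(m+n, m) splits
# of the pooled observed values.
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(m + n, m)
  Ws <- apply(splits, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mu <- m * n / 2
  # two-sided: mass at least as far from the null mean as observed
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

rbvn <- function(n, mean, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(2 * n), ncol = 2) %*% L +
    matrix(mean, n, 2, byrow = TRUE)
}
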