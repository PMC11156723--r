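# Rank-based group comparisons implemented on mid-ranks with explicit tie
# corrections: Kruskal-Wallis, Dunn's post hoc z tests, the Wilcoxon
# (Mann-Whitney) rank-sum test with exact small-sample null, and
# rank-based effect sizes.

new_test_result <- function(statistic, df, p_value, method, n_per_group) {
  structure(list(statistic = statistic, df = df,
                 p_value = min(max(p_value, 0), 1), method = method,
                 n_per_group = n_per_group),
            class = "residue_test")
}

#' @export
print.residue_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g%s, p-value = %.4g\n", x$statistic,
              if (is.null(x$df) || is.na(x$df)) "" else
                sprintf(", df = %d", x$df), x$p_value))
  invisible(x)
}

check_grouped <- function(values, groups, min_groups = 2) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  k <- length(unique(groups))
  if (k < min_groups)
    stop(sprintf("need at least %d groups with data, got %d", min_groups, k),
         call. = FALSE)
  list(values = values, groups = groups)
}

# Tie-correction term sum(t^3 - t) over tied-value run lengths t.
tie_term <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank sum test
#'
#' The H statistic on pooled mid-ranks with the standard tie correction,
#' referred to the chi-square distribution with k - 1 degrees of freedom.
#' When every observation is tied the statistic is defined as 0 (p = 1).
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`; at least 2 groups.
#' @return A `residue_test` with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  d <- check_grouped(values, groups)
  n <- length(d$values)
  r <- rank(d$values)
  ns <- tapply(r, d$groups, length)
  rs <- tapply(r, d$groups, sum)
  k <- length(ns)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  corr <- 1 - tie_term(d$values) / (n^3 - n)
  if (corr <= 0) {
    H <- 0
  } else {
    H <- H / corr
  }
  H <- max(H, 0)
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  new_test_result(H, k - 1L, p, "Kruskal-Wallis rank sum test (tie-corrected)",
                  as.integer(ns))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled mid-ranks with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tied runs. P-values are two-sided and
#' adjusted for multiplicity (default Holm).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment: `"holm"` (default), `"none"`,
#'   `"bonferroni"` or `"bh"`.
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `z`, `p_value` (adjusted).
#' @export
dunn_posthoc <- function(values, groups, adjust = c("holm", "none",
                                                    "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  d <- check_grouped(values, groups, min_groups = 3)
  n <- length(d$values)
  r <- rank(d$values)
  levs <- sort(unique(d$groups))
  ns <- vapply(levs, function(g) sum(d$groups == g), numeric(1))
  rbar <- vapply(levs, function(g) mean(r[d$groups == g]), numeric(1))
  Tt <- tie_term(d$values)
  base_var <- n * (n + 1) / 12 - Tt / (12 * (n - 1))
  pairs <- utils::combn(seq_along(levs), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(base_var * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = switch(adjust, bh = "BH", adjust))
  data.frame(group1 = levs[pairs[1, ]], group2 = levs[pairs[2, ]],
             z = z, p_value = pmin(p_adj, 1), stringsAsFactors = FALSE)
}

# Exact null distribution of the Mann-Whitney W statistic (tie-free case):
# counts, over all C(m+n, m) equally likely rank assignments, the number of
# size-m subsets of ranks 1..m+n with each possible rank sum, by a
# subset-sum dynamic program. Returns P(W <= w) as a function.
mann_whitney_exact_cdf <- function(m, n) {
  N <- m + n
  smax <- sum((n + 1):N)          # largest possible rank sum of the x sample
  # g[j + 1, s + 1] = number of size-j subsets of the ranks seen so far
  # with rank sum s
  g <- matrix(0, nrow = m + 1, ncol = smax + 1)
  g[1, 1] <- 1
  for (t in seq_len(N)) {
    cols <- seq.int(t + 1, smax + 1)
    g[2:(m + 1), cols] <- g[2:(m + 1), cols] + g[1:m, cols - t]
  }
  counts <- g[m + 1, ]            # indexed by rank sum s = 0..smax
  offset <- m * (m + 1) / 2       # W = ranksum - m(m+1)/2
  cum <- cumsum(counts) / choose(N, m)
  function(w) {
    s <- floor(w) + offset        # rank sum corresponding to W = w
    if (s < 0) 0 else if (s >= smax) 1 else cum[s + 1]
  }
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' The statistic `W` follows the Mann-Whitney convention of the first
#' sample: `W = sum(ranks of x in the pooled mid-rank ordering) -
#' n_x (n_x + 1) / 2`. Ties produce half-integer `W`. With no ties and a
#' small pooled sample the two-sided p-value is exact (full enumeration of
#' the null distribution); otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Use the exact null when tie-free and
#'   `length(x) * length(y) <= exact_max`; default 2500 (about 50 per
#'   group).
#' @return A `residue_test` with `statistic` (W) and two-sided `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 2500) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- any(duplicated(pooled))
  if (!has_ties && m * n <= exact_max) {
    cdf <- mann_whitney_exact_cdf(m, n)
    # two-sided: double the smaller tail (distribution symmetric about mn/2)
    lo <- cdf(W)
    hi <- 1 - (if (W >= 1) cdf(W - 1) else 0)
    p <- min(1, 2 * min(lo, hi))
    method <- "Wilcoxon rank sum test (exact)"
  } else {
    mu <- m * n / 2
    N <- m + n
    sig2 <- m * n / 12 * ((N + 1) - tie_term(pooled) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
    method <- "Wilcoxon rank sum test (normal approximation, tie-corrected)"
  }
  new_test_result(W, NA_integer_, p, method, c(m, n))
}

#' Rank-based effect size for a Kruskal-Wallis design
#'
#' Two standard effect sizes derived from the tie-corrected H statistic:
#' `eta2_h = (H - k + 1) / (n - k)` and
#' `epsilon2 = H / ((n^2 - 1) / (n + 1)) = H / (n - 1)`. Both are floored
#' at 0 (and capped at 1), since sampling noise can push the raw value
#' slightly outside \[0, 1\].
#'
#' @inheritParams kruskal_wallis
#' @param measure `"eta2_h"` (default) or `"epsilon2"`.
#' @return Effect size in \[0, 1\].
#' @export
kw_effect_size <- function(values, groups, measure = c("eta2_h", "epsilon2")) {
  measure <- match.arg(measure)
  d <- check_grouped(values, groups)
  n <- length(d$values)
  k <- length(unique(d$groups))
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  H <- kruskal_wallis(d$values, d$groups)$statistic
  raw <- switch(measure,
                eta2_h = (H - k + 1) / (n - k),
                epsilon2 = H / ((n^2 - 1) / (n + 1)))
  min(max(raw, 0), 1)
}
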