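test_that("Kruskal-Wallis handles degenerate ties and matches the base oracle", {
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))$statistic, 0)
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")

  # agreement with stats::kruskal.test (independent implementation),
  # with and without ties
  set.seed(21)
  for (i in 1:6) {
    g <- rep(c("a", "b", "c", "d")[1:sample(2:4, 1)], each = 7)
    v <- stats::rnorm(length(g)) + as.integer(factor(g)) * 0.4
    if (i %% 2 == 0) v <- round(v)           # induce ties
    mine <- kruskal_wallis(v, g)
    base <- stats::kruskal.test(v, factor(g))
    expect_equal(mine$statistic, unname(base$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(base$parameter))
  }
})

test_that("Kruskal-Wallis H equals the enumeration-oracle statistic on 3x3x3", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(1:3, each = 3)
  H <- kruskal_wallis(v, g)$statistic
  expect_equal(H, oracle_kw_h(v, g), tolerance = 1e-12)
  # exact permutation p from full enumeration bounds the chi-square p
  p_exact <- exact_perm_pvalue(v, c(3, 3, 3), oracle_kw_h, H)
  p_approx <- kruskal_wallis(v, g)$p_value
  expect_lt(abs(p_approx - p_exact), 0.05)
})

test_that("Dunn's test: degenerate ties, hand oracle, shifted-group detection", {
  allsame <- dunn_posthoc(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(allsame$z, rep(0, 3))
  expect_equal(allsame$p_value, rep(1, 3))
  expect_error(dunn_posthoc(1:4, rep(c("a", "b"), 2)), "at least 3 groups")

  # hand computation for {1,2} {3,4} {5,6}: ranks 1..6, no ties
  # mean ranks 1.5, 3.5, 5.5; var term N(N+1)/12 = 3.5
  res <- dunn_posthoc(1:6, rep(c("a", "b", "c"), each = 2), adjust = "none")
  se <- sqrt(3.5 * (1 / 2 + 1 / 2))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "b"], -2 / se,
               tolerance = 1e-12)
  expect_equal(res$z[res$group1 == "a" & res$group2 == "c"], -4 / se,
               tolerance = 1e-12)
  # tie-corrected variance hand check: {1,1,2} {2,2,3} {3,4,4}
  v <- c(1, 1, 2, 2, 2, 3, 3, 4, 4); g <- rep(c("a", "b", "c"), each = 3)
  r <- rank(v)
  tt <- sum(sapply(table(v), function(t) t^3 - t))
  base_var <- 9 * 10 / 12 - tt / (12 * 8)
  rb <- tapply(r, g, mean)
  z_ab <- (rb[["a"]] - rb[["b"]]) / sqrt(base_var * (2 / 3))
  got <- dunn_posthoc(v, g, adjust = "none")
  expect_equal(got$z[got$group1 == "a" & got$group2 == "b"], z_ab,
               tolerance = 1e-12)

  # one group shifted by 2 pooled SD: only its pairs significant,
  # under every adjustment option
  set.seed(22)
  vals <- c(stats::rnorm(30), stats::rnorm(30), stats::rnorm(30) + 2)
  grp <- rep(c("g1", "g2", "g3"), each = 30)
  for (adj in c("none", "holm", "bonferroni", "bh")) {
    dn <- dunn_posthoc(vals, grp, adjust = adj)
    hit <- dn$p_value < 0.05
    involves3 <- dn$group1 == "g3" | dn$group2 == "g3"
    expect_true(all(hit[involves3]))
    expect_false(any(hit[!involves3]))
  }
})

test_that("Wilcoxon rank sum: conventions, exact null, base-oracle agreement", {
  # complete separation
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$statistic, 0)
  # identical multisets: W = mn/2, p about 1 (mid-rank ties)
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_gt(r$p_value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")

  # half-integer W signals ties
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 5), c(2, 3, 6))$statistic, 3)

  # exact p equals wilcox.test's exact p on tie-free data
  set.seed(23)
  for (i in 1:6) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- stats::rnorm(m); y <- stats::rnorm(n) + 0.8
    mine <- wilcoxon_rank_sum(x, y)
    base <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(base$statistic))
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)
  }
  # tie-corrected normal approximation matches wilcox.test with correction
  xt <- c(1, 2, 2, 5, 7, 3); yt <- c(2, 3, 6, 6, 4)
  mine <- wilcoxon_rank_sum(xt, yt)
  base <- suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE))
  expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(24)
  v <- stats::rnorm(24); g <- rep(c("a", "b", "c"), each = 8)
  tr <- function(x) exp(x)          # strictly increasing
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(tr(v), g)$statistic, tolerance = 1e-12)
  expect_equal(dunn_posthoc(v, g)$z, dunn_posthoc(tr(v), g)$z,
               tolerance = 1e-12)
  x <- v[1:10]; y <- v[11:24]
  expect_equal(wilcoxon_rank_sum(x, y)$statistic,
               wilcoxon_rank_sum(tr(x), tr(y))$statistic)
})

test_that("two-group Kruskal-Wallis is consistent with the rank-sum test", {
  set.seed(25)
  x <- stats::rnorm(30); y <- stats::rnorm(35) + 0.5
  pk <- kruskal_wallis(c(x, y), rep(c("x", "y"), c(30, 35)))$p_value
  pw <- wilcoxon_rank_sum(x, y)$p_value
  expect_lt(abs(pk - pw), 0.02)
})

test_that("effect sizes are floored, bounded and grow with separation", {
  v0 <- rep(c(1, 1, 2, 2), 3); g0 <- rep(c("a", "b", "c"), each = 4)
  expect_gte(kw_effect_size(v0, g0, "eta2_h"), 0)
  # maximally separated groups approach the statistic's ceiling (for k = 3
  # equal groups the perfect-separation value is about 0.89) and dominate
  # an overlapping configuration
  v1 <- c(1:20, 101:120, 201:220); g1 <- rep(c("a", "b", "c"), each = 20)
  e_sep <- kw_effect_size(v1, g1, "eta2_h")
  expect_gt(e_sep, 0.85)
  expect_gt(kw_effect_size(v1, g1, "epsilon2"), 0.85)
  set.seed(27)
  v_overlap <- stats::rnorm(60) + rep(c(0, 0.3, 0.6), each = 20)
  expect_gt(e_sep, kw_effect_size(v_overlap, g1, "eta2_h"))
  set.seed(26)
  for (i in 1:10) {
    v <- stats::rnorm(30); g <- rep(c("a", "b", "c"), 10)
    for (ms in c("eta2_h", "epsilon2")) {
      e <- kw_effect_size(v, g, ms)
      expect_gte(e, 0); expect_lte(e, 1)
    }
  }
  expect_error(kw_effect_size(c(1, 2, 3), c("a", "b", "c")), "more observations")
})
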