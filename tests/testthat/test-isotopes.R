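test_that("Suess correction: zero case, additive offset, inverse, fallback", {
  rec <- data.frame(year = c(1850, 1950, 2020),
                    d13c_atm = c(-6.4, -6.9, -8.4))
  # record equal to the pre-industrial reference -> unchanged
  expect_equal(suess_correct(-30, 1850, rec), -30)
  # offset of 2.0 permil below reference -> +2.0 correction
  expect_equal(suess_correct(-30, 2020, rec), -28)
  # interpolation between record points
  expect_equal(suess_correct(-30, 1900, rec), -30 + 0.25)
  # applying the correction then subtracting it recovers the input
  x <- -27.3
  corr <- suess_correct(x, 2020, rec) - x
  expect_equal(suess_correct(x, 2020, rec) - corr, x, tolerance = 1e-12)
  # out-of-record year errors
  expect_error(suess_correct(-30, 2050, rec), "outside")
  # constant fallback without a record: only post-2010 samples shift
  expect_equal(suess_correct(-30, 2015), -28.1)
  expect_equal(suess_correct(-30, 1995), -30)
  # pre-industrial samples never corrected
  expect_equal(suess_correct(-30, 1700, rec), -30)
})

test_that("reference ellipse center and degenerate inputs", {
  theta <- seq(0, 2 * pi, length.out = 37)[-37]
  pts <- cbind(-30 + cos(theta), -30 + sin(theta))
  e <- fit_reference_ellipse(pts, 0.68)
  expect_equal(e$center, c(-30, -30), tolerance = 1e-9)
  expect_equal(e$n_ref, 36)
  expect_error(fit_reference_ellipse(pts[1:2, ]), "at least 3")
  dup <- matrix(rep(c(-30, -30), 5), ncol = 2, byrow = TRUE)
  expect_error(fit_reference_ellipse(dup), "singular")
  collinear <- cbind(1:10, 2 * (1:10))
  expect_error(fit_reference_ellipse(collinear), "singular")
  expect_error(fit_reference_ellipse(pts, level = 1.2), "level")
})

test_that("ellipse boundary points sit on the Mahalanobis contour", {
  set.seed(7)
  pts <- rbvn(200, c(-28, -29), matrix(c(2, 0.8, 0.8, 1.5), 2))
  e <- fit_reference_ellipse(pts, 0.68)
  b <- ellipse_boundary(e, n = 60)
  d2 <- stats::mahalanobis(b, e$center, e$covariance)
  expect_equal(d2, rep(stats::qchisq(0.68, 2), nrow(b)), tolerance = 1e-8)
})

test_that("source assignment: center, far point, ordering, translation invariance", {
  set.seed(8)
  e1 <- fit_reference_ellipse(rbvn(300, c(-24, -22), diag(c(1, 1))), 0.68,
                              "Marine")
  e2 <- fit_reference_ellipse(rbvn(300, c(-33, -32), diag(c(0.8, 0.8))), 0.68,
                              "Rice")
  res <- assign_source(-24, -22, list(e1, e2))
  expect_equal(res$class_label[1], "Marine")
  expect_lt(res$mahalanobis[1], 0.3)
  expect_true(res$inside[1])
  expect_false(res$inside[res$class_label == "Rice"])
  # 10 sigma away on both axes -> outside
  far <- assign_source(-24 + 10, -22 + 10, list(e1))
  expect_false(far$inside[1])
  # distances sorted ascending
  expect_true(!is.unsorted(res$mahalanobis))
  # re-centering everything by the same offset leaves distances unchanged
  off <- c(3.7, -1.2)
  e1s <- e1; e1s$center <- e1$center + off
  shifted <- assign_source(-24 + off[1], -22 + off[2], list(e1s))
  expect_equal(shifted$mahalanobis, res$mahalanobis[res$class_label == "Marine"],
               tolerance = 1e-10)
})

test_that("inside/outside decisions agree with a direct quadratic-form oracle", {
  set.seed(9)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(4), 2)
    Sigma <- crossprod(A) + diag(0.3, 2)
    ctr <- stats::rnorm(2, -28, 3)
    e <- fit_reference_ellipse(rbvn(500, ctr, Sigma), 0.68)
    grid <- as.matrix(expand.grid(seq(ctr[1] - 6, ctr[1] + 6, length.out = 15),
                                  seq(ctr[2] - 6, ctr[2] + 6, length.out = 15)))
    Sinv <- solve(e$covariance)
    for (i in seq_len(nrow(grid))) {
      v <- grid[i, ] - e$center
      inside_oracle <- drop(t(v) %*% Sinv %*% v) <= stats::qchisq(0.68, 2)
      got <- assign_source(grid[i, 1], grid[i, 2], list(e))$inside
      expect_identical(got, inside_oracle)
    }
  }
})

test_that("Delta13C arithmetic and antisymmetry", {
  expect_equal(big_delta(-25, -25), 0)
  expect_equal(big_delta(-28, -25), -3)
  expect_true(is.na(big_delta(NA, -25)))
  set.seed(10)
  a <- stats::rnorm(20, -28, 3); b <- stats::rnorm(20, -28, 3)
  expect_equal(big_delta(a, b), -big_delta(b, a))
})

test_that("isotope mixing: identity, midpoint, convexity, monotonicity", {
  one <- data.frame(fraction = 1, conc_16 = 10, conc_18 = 5,
                    d13c_16 = -31.2, d13c_18 = -30.1)
  expect_equal(mix_isotopes(one),
               c(d13c_16 = -31.2, d13c_18 = -30.1))

  two <- data.frame(fraction = c(0.5, 0.5), conc_16 = c(2, 2),
                    conc_18 = c(2, 2), d13c_16 = c(-30, -20),
                    d13c_18 = c(-32, -22))
  expect_equal(mix_isotopes(two), c(d13c_16 = -25, d13c_18 = -27))

  set.seed(11)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    f <- stats::rgamma(k, 1); f <- f / sum(f)
    spec <- data.frame(fraction = f,
                       conc_16 = stats::rlnorm(k, 2, 1),
                       conc_18 = stats::rlnorm(k, 2, 1),
                       d13c_16 = stats::runif(k, -35, -15),
                       d13c_18 = stats::runif(k, -35, -15))
    m <- mix_isotopes(spec)
    expect_gte(m[["d13c_16"]], min(spec$d13c_16) - 1e-9)
    expect_lte(m[["d13c_16"]], max(spec$d13c_16) + 1e-9)
    expect_gte(m[["d13c_18"]], min(spec$d13c_18) - 1e-9)
    expect_lte(m[["d13c_18"]], max(spec$d13c_18) + 1e-9)
  }

  # raising one component's concentration pulls the mix toward it
  base <- data.frame(fraction = c(0.5, 0.5), conc_16 = c(1, 1),
                     conc_18 = c(1, 1), d13c_16 = c(-34, -20),
                     d13c_18 = c(-33, -21))
  richer <- base; richer$conc_16[2] <- 5; richer$conc_18[2] <- 5
  expect_gt(mix_isotopes(richer)[["d13c_16"]], mix_isotopes(base)[["d13c_16"]])

  bad <- base; bad$fraction <- c(0.6, 0.6)
  expect_error(mix_isotopes(bad), "sum to 1")
  bad2 <- base; bad2$conc_16[1] <- 0
  expect_error(mix_isotopes(bad2), "positive")
})
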