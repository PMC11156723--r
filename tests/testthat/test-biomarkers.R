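test_that("E/H ratio arithmetic, missing-isomer and degenerate cases", {
  expect_equal(compute_eh_ratio(c(E = 12, H = 2)), 6.0)
  expect_equal(compute_eh_ratio(c(E = 5, H = 5)), 1.0)
  expect_true(is.na(compute_eh_ratio(c(A = 3, H = 2))))   # E absent
  expect_true(is.na(compute_eh_ratio(c(E = 3, H = 0))))   # zero denominator
  expect_true(is.na(compute_eh_ratio(c(E = NA, H = 2))))
  expect_error(compute_eh_ratio(c(E = -1, H = 2)), "non-negative")
})

test_that("E/H ratio is invariant under positive rescaling of all areas", {
  set.seed(101)
  for (i in 1:50) {
    areas <- stats::setNames(stats::rlnorm(9, 3, 1), LETTERS[1:9])
    k <- stats::rlnorm(1, 0, 2)
    expect_equal(compute_eh_ratio(areas * k), compute_eh_ratio(areas),
                 tolerance = 1e-12)
  }
})

test_that("cereal criterion is strict at the threshold and monotone", {
  expect_true(classify_cereal(8.0))
  expect_false(classify_cereal(6.0))     # strictly greater than 6
  expect_false(classify_cereal(1.0))
  expect_true(is.na(classify_cereal(NA_real_)))
  # monotone non-decreasing in the ratio for a fixed threshold
  ratios <- seq(0, 12, by = 0.5)
  calls <- classify_cereal(ratios)
  expect_true(all(diff(as.integer(calls)) >= 0))
  expect_true(classify_cereal(6.0, threshold = 5.9))
})

test_that("aquatic classification satisfies each documented criterion", {
  crit <- aquatic_criteria()
  res <- classify_aquatic(list(apaa_c22_area = 5), crit)
  expect_true(res$aquatic)
  expect_equal(res$evidence, "apaa_c22")

  res <- classify_aquatic(list(phytanic_srr_pct = 80), crit)
  expect_true(res$aquatic)
  expect_equal(res$evidence, "srr")
  # strict threshold
  expect_false(classify_aquatic(list(phytanic_srr_pct = 75), crit)$aquatic)

  # C20 relative to total C18 APAA
  s <- list(apaa_c20_area = 10, apaa_c18_A = 50, apaa_c18_E = 50,
            apaa_c18_H = 50)
  res <- classify_aquatic(s, crit)
  expect_true("apaa_ratio" %in% res$evidence)   # 10/150 = 0.067 > 0.06
  s$apaa_c20_area <- 0.5
  expect_false("apaa_ratio" %in% classify_aquatic(s, crit)$evidence)

  # nothing present -> negative call with empty evidence
  res <- classify_aquatic(list(phytanic_srr_pct = 50), crit)
  expect_false(res$aquatic)
  expect_length(res$evidence, 0)

  # isoprenoids alone are supporting evidence, never sufficient
  res <- classify_aquatic(list(pristanic_present = TRUE), crit)
  expect_false(res$aquatic)
})

test_that("aquatic classification is monotone in added evidence", {
  crit <- aquatic_criteria()
  base <- list(phytanic_srr_pct = 80)
  stopifnot(classify_aquatic(base, crit)$aquatic)
  richer <- list(phytanic_srr_pct = 80, apaa_c20_area = 5, apaa_c22_area = 3,
                 pristanic_present = TRUE)
  res <- classify_aquatic(richer, crit)
  expect_true(res$aquatic)
  expect_true(all(c("srr", "apaa_c20", "apaa_c22", "isoprenoids") %in%
                    res$evidence))
})

test_that("strict AND-mode requires isoprenoid support for APAA evidence", {
  crit <- aquatic_criteria(require_isoprenoid = TRUE)
  expect_false(classify_aquatic(list(apaa_c22_area = 5), crit)$aquatic)
  expect_true(classify_aquatic(list(apaa_c22_area = 5,
                                    pristanic_present = TRUE), crit)$aquatic)
  # SRR remains sufficient on its own
  expect_true(classify_aquatic(list(phytanic_srr_pct = 90), crit)$aquatic)
})

test_that("full sample classification combines all criteria deterministically", {
  s <- list(sample_id = "S1", site = "Tenshoji", phase = "EarlyYayoi",
            apaa_c18_E = 35, apaa_c18_H = 5, miliacin_present = TRUE)
  cl <- classify_sample(s)
  expect_equal(cl$eh_ratio, 7)
  expect_true(cl$cereal_consistent)
  expect_true(cl$millet)

  empty <- list(sample_id = "S2", site = "X", phase = "other")
  cl2 <- classify_sample(empty)
  expect_true(is.na(cl2$eh_ratio))
  expect_true(is.na(cl2$cereal_consistent))
  expect_false(cl2$aquatic)
  expect_false(cl2$millet)
  expect_false(cl2$resin)
})

test_that("batch classification equals row-wise application on a full table", {
  rt <- gen_residue_table(synth_config(seed = 9))
  batch <- classify_samples(rt$samples)
  rowwise <- do.call(rbind, lapply(seq_len(nrow(rt$samples)), function(i)
    classify_sample(rt$samples[i, , drop = FALSE])))
  rownames(rowwise) <- NULL
  expect_equal(batch, rowwise)
  # cereal_consistent missing exactly when eh_ratio is missing
  expect_equal(is.na(batch$cereal_consistent), is.na(batch$eh_ratio))
  # aquatic calls always carry evidence
  expect_true(all(nzchar(batch$aquatic_evidence[batch$aquatic])))
})

test_that("flag summaries conserve totals and match generator bookkeeping", {
  cl3 <- data.frame(site = c("A", "A", "B"), phase = "other",
                    millet = c(TRUE, FALSE, FALSE), aquatic = FALSE,
                    cereal_consistent = NA, resin = FALSE)
  sm <- summarize_flags(cl3, by = "site")
  expect_equal(sum(sm$n), 3)
  expect_equal(sm$millet[sm$site == "A"], 1)

  rt <- gen_residue_table(synth_config(seed = 31))
  cl <- classify_samples(rt$samples)
  sm <- summarize_flags(cl, by = c("site", "phase"))
  expect_equal(sum(sm$n), nrow(rt$samples))
  expect_equal(sum(sm$millet), sum(rt$samples$miliacin_present))
  # per-site miliacin counts agree with direct tabulation of the truth
  tab <- tapply(rt$samples$miliacin_present, rt$samples$site, sum)
  for (s in names(tab))
    expect_equal(sum(sm$millet[sm$site == s]), unname(tab[s]))
})
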