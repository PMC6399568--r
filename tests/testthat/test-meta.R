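test_that("study_effect reproduces the printed per-study intervals", {
  e <- study_effect(20, 181753, 77, 1534190)
  expect_equal(e$rr, 2.19, tolerance = 0.0075)
  expect_equal(e$ci_low, 1.34, tolerance = 0.0075)
  expect_equal(e$ci_high, 3.58, tolerance = 0.0075)
  e6 <- study_effect(3, 2884, 17, 87481)
  expect_equal(e6$rr, 5.35, tolerance = 0.0075)
  expect_equal(e6$ci_low, 1.57, tolerance = 0.0075)
  expect_equal(e6$ci_high, 18.26, tolerance = 0.0075)
  # equal rates: rr 1 with a log-symmetric interval
  eq <- study_effect(5, 100, 15, 300)
  expect_equal(eq$rr, 1)
  expect_equal(eq$ci_low * eq$ci_high, 1, tolerance = 1e-12)
  expect_error(study_effect(0, 10, 5, 20), "positive")
})

test_that("every printed per-study rr/CI cell is reproduced", {
  printed <- list(
    occ1 = cbind(rr = c(1.18, 2.19, 2.48, 1.49, 2.03, 5.35),
                 lo = c(0.16, 1.34, 0.55, 1.01, 0.99, 1.57),
                 hi = c(8.97, 3.58, 11.17, 2.19, 4.13, 18.26)),
    allocc = cbind(rr = c(2.23, 3.00, 3.03, 1.67, 2.70, 5.36),
                   lo = c(0.78, 2.26, 0.86, 1.22, 1.57, 2.02),
                   hi = c(6.33, 3.97, 10.62, 2.28, 4.66, 14.20)))
  for (ep in names(printed)) {
    ef <- with(ppi_raw[[ep]], study_effect(n1, P1, n2, P2))
    expect_true(all(abs(ef$rr - printed[[ep]][, "rr"]) < 0.0075))
    expect_true(all(abs(ef$ci_low - printed[[ep]][, "lo"]) < 0.0075))
    expect_true(all(abs(ef$ci_high - printed[[ep]][, "hi"]) < 0.0075))
  }
})

test_that("fixed-effect pooling matches the printed summary and metafor", {
  ef <- study_effects(ppi_fixture("first_occurrence"))
  fe <- fixed_effect(ef)
  expect_equal(fe$pooled_rr, 1.87, tolerance = 0.01)
  expect_equal(fe$ci_low, 1.43, tolerance = 0.01)
  expect_equal(fe$ci_high, 2.45, tolerance = 0.01)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = ef$log_rr, vi = ef$variance, method = "FE")
  expect_equal(fe$log_rr, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(fe$se, m$se, tolerance = 1e-10)
})

test_that("DerSimonian-Laird estimation matches metafor and truncates", {
  efA <- study_effects(ppi_fixture("all_occurrences"))
  re <- random_effects_dl(efA)
  expect_lt(abs(re$tau2 - 0.07), 0.011)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = efA$log_rr, vi = efA$variance, method = "DL")
  expect_equal(re$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(re$log_rr, as.numeric(m$beta), tolerance = 1e-10)
  # homogeneous effects truncate to zero and collapse onto fixed effect
  hom <- study_effect(c(10, 20), c(100, 200), c(10, 20), c(300, 600))
  expect_equal(random_effects_dl(hom)$tau2, 0)
  expect_equal(random_effects_dl(hom)$pooled_rr,
               fixed_effect(hom)$pooled_rr)
})

test_that("random-effects intervals contain the fixed-effect interval", {
  efA <- study_effects(ppi_fixture("all_occurrences"))
  fe <- fixed_effect(efA); re <- random_effects_dl(efA)
  expect_lte(re$ci_low, fe$ci_low)
  expect_gte(re$ci_high, fe$ci_high)
  # pooled estimates stay inside the span of the study estimates
  for (r in list(fe, re)) {
    expect_gte(r$pooled_rr, min(efA$rr))
    expect_lte(r$pooled_rr, max(efA$rr))
  }
  # with zero heterogeneity the two models coincide
  ef1 <- study_effects(ppi_fixture("first_occurrence"))
  re1 <- random_effects_dl(ef1)
  expect_equal(re1$tau2, 0)
  expect_equal(re1$pooled_rr, fixed_effect(ef1)$pooled_rr)
})

test_that("pooling identical studies shrinks the interval by sqrt(2)", {
  one <- study_effect(20, 100, 30, 300)
  two <- study_effect(c(20, 20), c(100, 100), c(30, 30), c(300, 300))
  f1 <- fixed_effect(one); f2 <- fixed_effect(two)
  expect_equal(f2$pooled_rr, f1$pooled_rr)
  expect_equal(log(f1$ci_high / f1$ci_low),
               sqrt(2) * log(f2$ci_high / f2$ci_low))
  # a single study returns its own effect
  expect_equal(f1$pooled_rr, one$rr)
  expect_equal(f1$ci_low, one$ci_low)
})

test_that("the Z test rejects exactly when the interval excludes 1", {
  fe <- fixed_effect(study_effects(ppi_fixture("first_occurrence")))
  expect_true(meta_z_test(fe, alpha = 0.05))
  flat <- fixed_effect(study_effect(10, 100, 30, 300))
  expect_false(meta_z_test(flat, alpha = 0.05))
})

test_that("zero-count studies are excluded or continuity-corrected", {
  t0 <- study_table(c(0, 10), c(50, 500), rows = c("A", "B"), study = "z")
  t1 <- study_table(c(5, 10), c(50, 500), rows = c("A", "B"), study = "ok")
  ms <- multi_study(t0, t1)
  expect_warning(ef <- study_effects(ms), "zero-count")
  expect_equal(nrow(ef), 1L)
  ef2 <- study_effects(ms, zero_counts = "continuity")
  expect_equal(nrow(ef2), 2L)
  expect_equal(ef2$n1[ef2$study == "z"], 0.5)
})

test_that("forest_table carries the studies plus one summary row", {
  ef <- study_effects(ppi_fixture("first_occurrence"))
  fe <- fixed_effect(ef)
  ft <- forest_table(ef, fe)
  expect_equal(nrow(ft), 7L)
  expect_equal(sum(ft$summary), 1L)
  expect_equal(sum(ft$weight, na.rm = TRUE), 1)
  expect_equal(ft$rr[ft$summary], fe$pooled_rr)
})
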