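test_that("pooled analysis reproduces the printed statistics", {
  r1 <- pooled_lrt(ppi_fixture("first_occurrence"), n_draws = 4000,
                   seed = 1)
  expect_equal(r1$statistic, 6.12, tolerance = 0.005)
  expect_identical(unname(r1$signal), "PLandPPI")
  expect_lt(r1$p_value, 0.01)
  rA <- pooled_lrt(ppi_fixture("all_occurrences"), n_draws = 4000,
                   seed = 1)
  expect_equal(rA$statistic, 34.27, tolerance = 0.005)
  expect_equal(rA$p_value, 0)
})

test_that("mmlr takes the maximum over studies and locates its source", {
  ppiA <- ppi_fixture("all_occurrences")
  r <- mmlr(ppiA, n_draws = 4000, seed = 2)
  expect_equal(r$statistic, 24.28, tolerance = 0.005)
  expect_identical(unname(r$signal), c("PLandPPI", "s2"))
  expect_equal(r$p_value, 0)
  # the global maximum dominates every study's own statistic
  mllr_s <- vapply(ppiA, function(t) max(study_loglr(t)), numeric(1))
  expect_true(all(r$statistic >= mllr_s))
  r1 <- mmlr(ppi_fixture("first_occurrence"), n_draws = 4000, seed = 2)
  expect_equal(r1$statistic, 4.16, tolerance = 0.005)
  expect_identical(unname(r1$signal["study"]), "s2")
  expect_lt(r1$p_value, 0.05)
})

test_that("wlrn weights each study's statistic by its total exposure", {
  ppi1 <- ppi_fixture("first_occurrence")
  r <- wlrn(ppi1, n_draws = 4000, seed = 3)
  expect_equal(r$statistic, 2.81, tolerance = 0.005)
  expect_lt(r$p_value, 0.05)
  rA <- wlrn(ppi_fixture("all_occurrences"), n_draws = 4000, seed = 3)
  expect_equal(rA$statistic, 14.02, tolerance = 0.005)
  # independent recomputation of the weighted average for the signal row
  with(ppi_raw$occ1, {
    l <- mapply(function(a, b, c, d)
      max(study_loglr(two_row_table(a, b, c, d))), n1, P1, n2, P2)
    w <- P1 + P2
    expect_equal(r$statistic, sum(w * l) / sum(w))
  })
})

test_that("wlrn weight modes behave as documented", {
  ppi1 <- ppi_fixture("first_occurrence")
  base <- wlrn(ppi1, n_draws = 200, seed = 4)
  # row-exposure weights give a different combination on this data
  rowe <- wlrn(ppi1, n_draws = 200, seed = 4, weight_mode = "row_exposure")
  with(ppi_raw$occ1, {
    l <- mapply(function(a, b, c, d)
      max(study_loglr(two_row_table(a, b, c, d))), n1, P1, n2, P2)
    expect_equal(rowe$statistic, sum(P1 * l) / sum(P1))
  })
  # equal custom weights reduce to the plain average
  eq <- wlrn(ppi1, n_draws = 200, seed = 4, weight_mode = "custom",
             weights = rep(2, 6))
  with(ppi_raw$occ1, {
    l <- mapply(function(a, b, c, d)
      max(study_loglr(two_row_table(a, b, c, d))), n1, P1, n2, P2)
    expect_equal(eq$statistic, mean(l))
  })
  expect_error(wlrn(ppi1, weight_mode = "custom"), "weights")
  # a constant per-study statistic is preserved by any weighting
  same <- multi_study(lapply(1:3, function(s)
    study_table(c(9, 2), c(100, 100), rows = c("A", "B"),
                study = paste0("s", s))))
  for (mode in c("study_total_exposure", "row_exposure")) {
    r <- wlrn(same, n_draws = 100, seed = 1, weight_mode = mode)
    expect_equal(r$statistic,
                 max(study_loglr(same[[1]])), tolerance = 1e-12)
  }
})

test_that("with a single study every combiner reduces to the regular LRT", {
  tab <- two_row_table(20, 181753, 77, 1534190, study = "s2")
  ms <- multi_study(list(tab))
  ref <- regular_lrt(tab, n_draws = 500, seed = 5)
  expect_equal(pooled_lrt(ms, 500, seed = 5)$statistic, ref$mllr)
  expect_equal(mmlr(ms, 500, seed = 5)$statistic, ref$mllr)
  for (mode in c("study_total_exposure", "row_exposure"))
    expect_equal(wlrn(ms, 500, seed = 5, weight_mode = mode)$statistic,
                 ref$mllr)
  # and the mmlr null sample is the regular null sample itself
  expect_equal(mmlr(ms, 500, seed = 5)$null_sample, ref$null_sample)
})

test_that("the weighted statistic lies between the studies it averages", {
  ppiA <- ppi_fixture("all_occurrences")
  r <- wlrn(ppiA, n_draws = 200, seed = 6)
  l <- vapply(ppiA, function(t) unname(study_loglr(t)["PLandPPI"]),
              numeric(1))
  expect_gte(r$statistic, min(l))
  expect_lte(r$statistic, max(l))
})

test_that("global step-down finds the secondary study signals", {
  r <- mmlr(ppi_fixture("all_occurrences"), n_draws = 10000, seed = 7)
  sd <- global_step_down(r, alpha = 0.05)
  expect_setequal(sd$study[sd$signal], c("s2", "s4", "s5", "s6"))
  expect_true(all(sd$row[sd$signal] == "PLandPPI"))
  expect_identical(sd$signal_rank[1], 1L)
  # a flat result has no signals
  flat <- multi_study(lapply(1:2, function(s)
    study_table(c(5, 15), c(100, 300), rows = c("A", "B"),
                study = paste0("s", s))))
  rf <- wlrn(flat, n_draws = 200, seed = 1)
  expect_equal(rf$statistic, 0)
  expect_equal(sum(global_step_down(rf)$signal), 0L)
})

test_that("a strongly elevated synthetic row is the detected signal", {
  eta <- rep(1, 27); eta[c(1, 3, 5, 7)] <- 3
  lip <- lipiodol_like(seed = 77, eta = eta)
  r <- wlrn(lip, n_draws = 2000, seed = 8)
  expect_true(unname(r$signal["row"]) %in% sprintf("AE%02d", c(1, 3, 5, 7)))
  expect_lt(r$p_value, 0.05)
  sd <- global_step_down(r)
  top <- sd$row[sd$signal]
  expect_true(all(top[1:2] %in% sprintf("AE%02d", c(1, 3, 5, 7))))
})

test_that("rows present in only some studies use their own study set", {
  t1 <- study_table(c(10, 20, 30), c(100, 100, 500),
                    rows = c("A", "B", "C"), study = "s1")
  t2 <- study_table(c(8, 40), c(100, 500), rows = c("A", "C"),
                    study = "s2")
  ms <- multi_study(t1, t2)
  r <- wlrn(ms, n_draws = 200, seed = 9)
  lb <- unname(study_loglr(t1)["B"])
  expect_gt(lb, 0)
  expect_equal(r$per_unit_stats$loglr[r$per_unit_stats$row == "B"], lb)
  p <- pool_studies(ms)
  expect_equal(p$counts[p$rows == "B"], 20)
})
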