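ct <- function(a, b, c, d) contingency_table(a, b, c, d, entity = "X")

test_that("haldane_adjust adds 0.5 to all four cells only when a cell is zero", {
  adj <- haldane_adjust(ct(9, 0, 83, 196))
  expect_identical(c(adj$a, adj$b, adj$c, adj$d), c(9.5, 0.5, 83.5, 196.5))
  expect_true(adj$corrected)
  expect_identical(adj$n_case_mentions, 9L)  # pre-correction count kept
  un <- haldane_adjust(ct(2, 3, 4, 5))
  expect_identical(c(un$a, un$b, un$c, un$d), c(2, 3, 4, 5))
  expect_false(un$corrected)
  two0 <- haldane_adjust(ct(9, 0, 0, 3))
  expect_identical(c(two0$a, two0$b, two0$c, two0$d), c(9.5, 0.5, 0.5, 3.5))
})

test_that("compute_ror matches published point estimates and Woolf CIs", {
  r <- compute_ror(ct(20, 19, 14, 43))
  expect_identical(round_half_up(r$ror, 2), 3.23)
  expect_identical(round_half_up(r$ci_low, 2), 1.35)
  expect_identical(round_half_up(r$ci_high, 2), 7.72)

  r <- compute_ror(haldane_adjust(ct(9, 0, 0, 3)))
  expect_identical(round_half_up(r$ror, 2), 133)
  expect_identical(round_half_up(r$ci_low, 2), 2.19)
  expect_identical(round_half_up(r$ci_high, 2), 8082.55)

  r <- compute_ror(ct(5, 5, 47, 173))
  expect_identical(round_half_up(r$ror, 2), 3.68)
  expect_identical(round_half_up(r$ci_low, 2), 1.02)
  expect_identical(round_half_up(r$ci_high, 2), 13.25)

  expect_identical(compute_ror(ct(1, 1, 1, 1))$ror, 1)
  expect_error(compute_ror(ct(9, 0, 83, 196)), "haldane_adjust")
})

test_that("ROR obeys reciprocity, transposition and CI log-symmetry", {
  set.seed(42)
  for (i in 1:50) {
    cells <- stats::rpois(4, 20) + 1
    r1 <- compute_ror(ct(cells[1], cells[2], cells[3], cells[4]))
    r2 <- compute_ror(ct(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(log(r1$ror), -log(r2$ror), tolerance = 1e-12)
    expect_equal(log(r1$ci_low), -log(r2$ci_high), tolerance = 1e-12)
    # transposing exposure and outcome leaves the odds ratio unchanged
    r3 <- compute_ror(ct(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(r1$ror, r3$ror, tolerance = 1e-12)
    # log-symmetric CI
    expect_equal(log(r1$ci_high) - log(r1$ror),
                 log(r1$ror) - log(r1$ci_low), tolerance = 1e-12)
    expect_true(r1$ci_low <= r1$ror && r1$ror <= r1$ci_high)
  }
})

test_that("evaluate_signal: each criterion is independently binding", {
  res <- compute_ror(ct(20, 19, 14, 43))  # ROR 3.23, ci_low 1.35, a = 20
  expect_true(evaluate_signal(res))
  expect_false(evaluate_signal(res, signal_criteria(min_ror = 4)))
  expect_false(evaluate_signal(res, signal_criteria(min_ci_low = 1.5)))
  expect_false(evaluate_signal(res, signal_criteria(min_cases = 21)))
  # boundary: ROR >= 2 inclusive, ci_low > 1 strict, cases >= 5 inclusive
  expect_true(evaluate_signal(res, signal_criteria(min_ror = res$ror)))
  expect_false(evaluate_signal(res, signal_criteria(min_ci_low = res$ci_low)))
  expect_error(signal_criteria(min_ror = 0), "positive")
})

test_that("pearson_chi2 matches stats::chisq.test without continuity correction", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(stats::rpois(6, 30) + 1, 2, 3)
    ours <- pearson_chi2(tab)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_identical(ours$df, 2L)
    expect_equal(ours$p, unname(oracle$p.value), tolerance = 1e-12)
  }
  # proportional rows are exactly independent
  expect_equal(pearson_chi2(rbind(c(10, 20, 30), c(5, 10, 15)))$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(pearson_chi2(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("two_sample_t_equal_var equals t.test on raw data and is antisymmetric", {
  set.seed(11)
  x <- stats::rnorm(40, 55, 20)
  y <- stats::rnorm(70, 50, 22)
  ours <- two_sample_t_equal_var(mean(x), stats::sd(x), length(x),
                                 mean(y), stats::sd(y), length(y))
  oracle <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(oracle$parameter), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-10)
  swapped <- two_sample_t_equal_var(mean(y), stats::sd(y), length(y),
                                    mean(x), stats::sd(x), length(x))
  expect_equal(ours$t, -swapped$t)
  expect_equal(two_sample_t_equal_var(5, 1, 10, 5, 2, 12)$t, 0)
  # pooled t from the published cohort summaries
  expect_equal(
    round_half_up(two_sample_t_equal_var(59.56, 21.6, 202,
                                         50.00, 22.1, 1087)$t, 2), 5.67)
  expect_error(two_sample_t_equal_var(1, 1, 1, 2, 1, 5), "n >= 2")
  expect_error(two_sample_t_equal_var(1, 0, 5, 2, 1, 5), "must be > 0")
})

test_that("proportion_pct rounds half-up to one decimal", {
  expect_identical(proportion_pct(352, 53505), 0.7)
  expect_identical(proportion_pct(32, 335), 9.6)
  expect_identical(proportion_pct(0, 10), 0)
  expect_identical(proportion_pct(1, 16), 6.3)   # 6.25 rounds up
  expect_error(proportion_pct(1, 0), "denominator")
  expect_error(proportion_pct(5, 4), "numerator")
})

test_that("round_half_up breaks ties away from zero", {
  expect_identical(round_half_up(2.675, 2), 2.68)
  expect_identical(round_half_up(-2.675, 2), -2.68)
  expect_identical(round_half_up(2.5), 3)
  expect_identical(round_half_up(17.543, 1), 17.5)
})

test_that("ror_table runs the whole drug-level path and flags signals", {
  m <- counts_to_mentions()
  res <- ror_table(m, level = 5, comparator = "siblings_within_parent")
  expect_true(all(res$n_case_mentions >= 5))
  sig <- res$entity[res$signal]
  expect_true(all(c("B01AE07", "J05AF07", "V03AC03") %in% sig))
  expect_false("A10BA02" %in% sig)  # metformin ROR < 1
  # corrected tables flagged
  expect_true(res$corrected[res$entity == "L01EG02"])
  expect_false(res$corrected[res$entity == "B01AE07"])
})
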