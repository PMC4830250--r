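test_that("percentage deviation: definition, identity, scale-invariance", {
  expect_equal(percentage_deviation(11, 10), 10)
  expect_equal(percentage_deviation(9.85, 9.85), 0)
  expect_error(percentage_deviation(5, 0), "positive")
  set.seed(3)
  x <- runif(20, 1, 50); y <- runif(20, 1, 50); k <- 7.3
  expect_equal(percentage_deviation(k * x, k * y), percentage_deviation(x, y))
  expect_true(all(percentage_deviation(x, y) >= 0))
})

test_that("closest_value_counts: wins, ties, policies, sum invariant", {
  est <- cbind(v1 = 12, v2 = 10.5)
  r <- closest_value_counts(est, 10)
  expect_equal(r$counts, c(v1 = 0L, v2 = 1L))
  # exact tie: default policy awards the earlier-listed variation
  tie <- cbind(v1 = 8, v2 = 12)
  expect_equal(closest_value_counts(tie, 10)$counts, c(v1 = 1L, v2 = 0L))
  expect_equal(closest_value_counts(tie, 10, tie_policy = "last")$counts,
               c(v1 = 0L, v2 = 1L))
  picks <- vapply(1:2, function(s)
    which(closest_value_counts(tie, 10, tie_policy = "random",
                               seed = s)$counts == 1L), integer(1))
  expect_true(all(picks %in% 1:2))
  # counts sum to n under every policy, on random data with forced ties
  set.seed(9)
  for (pol in c("first", "last", "random")) {
    est <- matrix(sample(1:5, 60, TRUE), 20, 3)
    ref <- sample(1:5, 20, TRUE)
    cc <- closest_value_counts(est, ref, tie_policy = pol)
    expect_equal(sum(cc$counts), 20L)
  }
  expect_error(closest_value_counts(matrix(numeric(0), 0, 2), numeric(0)),
               "non-empty")
})

test_that("deviation_bins boundaries and permutation invariance", {
  expect_equal(unname(deviation_bins(c(5, 15, 25))), c(1L, 1L, 1L))
  expect_equal(unname(deviation_bins(c(10, 20))), c(0L, 2L, 0L))
  expect_error(deviation_bins(c(-1, 5)), "non-negative")
  set.seed(5)
  d <- runif(40, 0, 40)
  expect_equal(deviation_bins(d), deviation_bins(sample(d)))
  expect_equal(sum(deviation_bins(d)), 40L)
})

test_that("compare_means: identical samples, separated means, Levene gate", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_means(x, x)
  expect_equal(r$t_p, 1)
  expect_equal(r$variant_used, "pooled")
  a <- c(0, 0, 0, 0) + rnorm(4, sd = 1e-3)
  b <- c(10, 10, 10, 10) + rnorm(4, sd = 1e-3)
  expect_lt(compare_means(a, b)$t_p, 1e-6)
  # grossly unequal variances push through the Welch branch
  set.seed(8)
  r2 <- compare_means(rnorm(50, sd = 0.1), rnorm(50, sd = 30))
  expect_lt(r2$levene_p, 0.05)
  expect_equal(r2$variant_used, "welch")
  expect_error(compare_means(rep(1, 4), rep(2, 4)), "undefined")
})

test_that("bland_altman: degenerate and offset cases; Gaussian coverage", {
  x <- c(1, 5, 9, 12)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_difference_mL, 0)
  expect_equal(ba$loa_low_mL, 0)
  expect_equal(ba$loa_high_mL, 0)
  ba2 <- bland_altman(x + 5, x)
  expect_equal(ba2$mean_difference_mL, 5)
  expect_equal(ba2$sd_difference_mL, 0)
  expect_error(bland_altman(1:3, 1:4), "equal length")
  # limits hold about 95% of i.i.d. Gaussian differences
  set.seed(31)
  ref <- runif(1e5, 10, 50)
  est <- ref + rnorm(1e5, mean = 1, sd = 2)
  ba3 <- bland_altman(est, ref)
  expect_equal(ba3$proportion_within_loa, 0.95, tolerance = 0.005 / 0.95)
  expect_lte(ba3$loa_low_mL, ba3$mean_difference_mL)
  expect_lte(ba3$mean_difference_mL, ba3$loa_high_mL)
})

test_that("summarize_cohort recomputes a two-case-style toy table by hand", {
  tab <- data.frame(planimetry = c(10, 20, 40),
                    vA = c(11, 19, 44), vB = c(14, 26, 30))
  s <- summarize_cohort(tab, variations = c("vA", "vB"))
  rowA <- s$table[s$table$variation == "vA", ]
  expect_equal(rowA$mean_mL, mean(c(11, 19, 44)))
  expect_equal(rowA$dev_mean_pct, mean(c(10, 5, 10)))
  expect_equal(rowA$n_lt10, 1L)        # 5% only; the two 10s hit the bin edge
  expect_equal(rowA$n_10_20, 2L)
  expect_equal(rowA$closest_overall, 3L)
  rowB <- s$table[s$table$variation == "vB", ]
  expect_equal(rowB$closest_overall, 0L)
  expect_equal(rowB$dev_mean_pct, mean(c(40, 30, 25)))
  expect_equal(s$agreement$vA$mean_difference_mL, mean(c(1, -1, 4)))
  # permuting cases leaves the summary table unchanged
  s2 <- summarize_cohort(tab[c(3, 1, 2), ], variations = c("vA", "vB"))
  expect_equal(s2$table, s$table)
})

test_that("summarize_cohort accepts case_record lists", {
  recs <- list(
    case_record("a", 10, 40, 30, 38, 28, 25, 20),
    case_record("b", 30, 60, 40, 58, 38, 30, 25),
    case_record("c", 5, 30, 20, 28, 18, 20, 15))
  s <- summarize_cohort(recs)
  expect_equal(s$n, 3L)
  expect_equal(sum(s$table$closest_overall), 3L)
  expect_setequal(s$table$variation,
                  c("v1", "v2", "v3", "v4", "v1p", "v2p", "v3p", "v4p"))
})
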