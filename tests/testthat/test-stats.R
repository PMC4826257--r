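test_that("summaries use type-7 interpolated quartiles", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(c(s$lower_quartile, s$median, s$upper_quartile), c(2, 3, 4))
  s <- summarize_values(c(2, 4))
  expect_equal(c(s$lower_quartile, s$median, s$upper_quartile),
               c(2.5, 3, 3.5))
  s <- summarize_values(7)
  expect_equal(c(s$lower_quartile, s$median, s$upper_quartile), c(7, 7, 7))
  expect_error(summarize_values(numeric(0)), "non-empty")
})

test_that("exact rank-sum p equals full labeling enumeration", {
  r <- rank_sum_test(c(1, 2), c(3, 4), method = "exact")
  expect_equal(r$p_two_sided, enum_rank_sum_p(c(1, 2), c(3, 4)))
  expect_equal(r$p_two_sided, 2 / 6)
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- rnorm(n); y <- rnorm(m, mean = runif(1, -1, 1))
    r <- rank_sum_test(x, y, method = "exact")
    expect_equal(r$p_two_sided, enum_rank_sum_p(x, y))
    # base R's exact distribution as a second independent route
    expect_equal(r$p_two_sided,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("rank-sum test is symmetric, guards zero variance, flags ties", {
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(rank_sum_test(x, y)$p_two_sided,
               rank_sum_test(y, x)$p_two_sided)
  expect_equal(rank_sum_test(5, 5)$p_two_sided, 1)
  # under ties, exact mode is the conditional permutation distribution
  x <- c(1, 1, 2, 4); y <- c(1, 3, 3)
  expect_equal(rank_sum_test(x, y, method = "exact")$p_two_sided,
               enum_rank_sum_p(x, y))
  # the default resolution for tied data is the normal approximation
  expect_equal(rank_sum_test(x, y, method = "auto")$method,
               "normal_approx")
})

test_that("rank-sum normal approximation matches the classical formulas", {
  # tie-corrected, continuity-corrected variant against wilcox.test
  set.seed(7)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(2:9, 35, replace = TRUE)
    r <- rank_sum_test(x, y, method = "normal_approx")
    expect_equal(r$p_two_sided,
                 stats::wilcox.test(x, y, exact = FALSE,
                                    correct = TRUE)$p.value)
  }
})

test_that("exact signed-rank p equals full sign enumeration", {
  r <- signed_rank_test(c(1, 2, 3), method = "exact")
  expect_equal(r$p_two_sided, 2 / 8)
  expect_equal(r$p_two_sided, enum_signed_rank_p(c(1, 2, 3)))
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- rnorm(n)
    r <- signed_rank_test(d, method = "exact")
    expect_equal(r$p_two_sided, enum_signed_rank_p(d))
    expect_equal(r$p_two_sided,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("exact signed-rank distribution is complete and closed-form at one tail", {
  for (n in c(3, 8, 15)) {
    counts <- consurvey:::signed_rank_counts(2L * seq_len(n))
    expect_equal(sum(counts), 2^n)
  }
  # all-same-sign differences: two-sided p = 2^(1 - n)
  for (n in 1:25) {
    p <- signed_rank_test(seq_len(n) + 0.5, method = "exact")$p_two_sided
    expect_equal(p, min(1, 2^(1 - n)))
  }
})

test_that("signed-rank invariances and degenerate handling", {
  d <- c(-1.2, 0.4, 2.5, -3.1, 0.9, 1.7)
  expect_equal(signed_rank_test(d)$p_two_sided,
               signed_rank_test(-d)$p_two_sided)
  expect_message(r <- signed_rank_test(c(0, 0, 1, -2, 3)), "2 zero")
  expect_equal(r$n, 3L)
  expect_error(suppressMessages(signed_rank_test(c(0, 0))), "no nonzero")
  # tied magnitudes: exact mode matches the sign-assignment enumeration
  d <- c(1, -1, 2, -3, 3)
  expect_equal(signed_rank_test(d, method = "exact")$p_two_sided,
               enum_signed_rank_p(d))
  expect_equal(signed_rank_test(d, method = "auto")$method,
               "normal_approx")
})

test_that("signed-rank normal approximation matches wilcox.test with ties", {
  set.seed(11)
  for (i in 1:10) {
    d <- sample(c(-4:-1, 1:6), 40, replace = TRUE)
    r <- signed_rank_test(d, method = "normal_approx")
    expect_equal(r$p_two_sided,
                 stats::wilcox.test(d, exact = FALSE,
                                    correct = TRUE)$p.value)
  }
})

test_that("exact and normal-approximation p agree closely on tie-free samples", {
  # The approximation is a central-range tool: agreement is asserted
  # where the exact p is not in the extreme tail (p >= 0.05), which is
  # where both variants would ever be interchangeable.
  set.seed(99)
  # signed-rank, n in 15..25
  for (i in 1:50) {
    n <- sample(15:25, 1)
    d <- rnorm(n)
    pe <- signed_rank_test(d, method = "exact")$p_two_sided
    if (pe < 0.05) next
    pn <- signed_rank_test(d, method = "normal_approx")$p_two_sided
    expect_lt(abs(pn - pe) / pe, 0.15)
  }
  # rank-sum, n = m in 8..10
  for (i in 1:50) {
    n <- sample(8:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    pe <- rank_sum_test(x, y, method = "exact")$p_two_sided
    if (pe < 0.05) next
    pn <- rank_sum_test(x, y, method = "normal_approx")$p_two_sided
    expect_lt(abs(pn - pe) / pe, 0.15)
  }
})
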