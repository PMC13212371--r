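# Kockelkoren subtype classification and density-by-subtype comparisons.

test_that("the score partition is exhaustive: 0-4 intimal, 5-8 ambiguous,
          9-19 medial", {
  lab <- classify_subtype(0:19)
  expect_identical(as.character(lab),
                   c(rep("intimal", 5), rep("ambiguous", 4), rep("medial", 11)))
  expect_identical(as.integer(table(lab)), c(5L, 4L, 11L))
  expect_error(classify_subtype(-1), "0\\.\\.19")
  expect_error(classify_subtype(20), "0\\.\\.19")
  expect_error(classify_subtype(2.5), "integers")
})

test_that("density summaries stratify correctly and count scored arteries
          without measurable density", {
  arts <- data.frame(kockelkoren_score = c(1, 3, 12, 2),
                     mean_hu = c(210, 250, 300, NA))
  ds <- density_by_subtype(arts)
  expect_identical(ds$n_excluded, 1L)
  s <- ds$summary
  expect_identical(s$n, c(2L, 0L, 1L))
  expect_equal(s$median_hu[1], 230)
  expect_true(is.na(s$median_hu[2]))
  # singleton stratum: median is the value, IQR width zero
  expect_equal(s$median_hu[3], 300)
  expect_equal(s$q3_hu[3] - s$q1_hu[3], 0)
})

test_that("simulated subtype arteries recover their generating medians", {
  arts <- simulate_subtype_arteries(60000, seed = 99)
  ds <- density_by_subtype(arts)$summary
  gen <- c(210, 255, 294)
  expect_true(all(abs(ds$median_hu / gen - 1) < 0.02))
  expect_true(all(table(classify_subtype(arts$kockelkoren_score)) > 0))
  one <- simulate_subtype_arteries(500, weights = c(1, 0, 0), seed = 4)
  expect_true(all(one$kockelkoren_score < 5))
})

test_that("log-normal sigma from quartile matching back-calculates the IQR", {
  s <- lognormal_sdlog(179, 264)
  expect_equal(stats::qlnorm(0.75, log(210), s) / stats::qlnorm(0.25, log(210), s),
               264 / 179, tolerance = 1e-12)
})

test_that("the exact rank-sum p-value matches exhaustive enumeration of rank
          assignments", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- wilcoxon_rank_sum(x, y)
  expect_identical(r$method, "exact")
  # enumeration oracle: all C(6,3) assignments of pooled ranks to x
  pooled <- 1:6
  combos <- utils::combn(6, 3)
  u_obs <- sum(rank(c(x, y))[1:3]) - 3 * 4 / 2
  u_all <- apply(combos, 2, function(ix) sum(pooled[ix]) - 3 * 4 / 2)
  p_enum <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(r$p_value, p_enum)
  expect_equal(r$p_value, 0.1)
})

test_that("identical samples give U = n^2 / 2 and p near 1", {
  x <- c(3, 1, 4, 1, 5)
  r <- wilcoxon_rank_sum(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_gt(r$p_value, 0.95)
  expect_error(wilcoxon_rank_sum(numeric(0), x), "non-empty")
})

test_that("the normal approximation tracks a permutation oracle at n = 30
          per arm", {
  set.seed(31)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  r <- wilcoxon_rank_sum(x, y)
  expect_identical(r$method, "normal_approx")
  pooled <- c(x, y)
  u_obs <- r$statistic
  mu <- 30 * 30 / 2
  perm <- replicate(10000, {
    idx <- sample(60, 30)
    sum(rank(pooled)[idx]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(perm - mu) >= abs(u_obs - mu) - 1e-9)
  expect_lt(abs(r$p_value - p_perm), 0.01)
})

test_that("the rank-sum p-value is invariant under strictly monotone
          transforms of the pooled data", {
  set.seed(8)
  x <- rlnorm(12); y <- rlnorm(15, 0.5)
  r0 <- wilcoxon_rank_sum(x, y)
  r1 <- wilcoxon_rank_sum(log(x), log(y))
  r2 <- wilcoxon_rank_sum(x^3, y^3)
  expect_equal(r0$p_value, r1$p_value)
  expect_equal(r0$p_value, r2$p_value)
})

test_that("pairwise subtype tests produce three comparisons with optional
          Bonferroni and a Welch alternative", {
  arts <- simulate_subtype_arteries(600, seed = 12)
  pw <- pairwise_subtype_tests(arts)
  expect_identical(nrow(pw), 3L)
  expect_true(all(grepl("wilcoxon", pw$method)))
  expect_null(pw$p_adjusted)
  adj <- pairwise_subtype_tests(arts, adjust = "bonferroni")
  expect_equal(adj$p_adjusted, pmin(1, adj$p * 3))
  tt <- pairwise_subtype_tests(arts, test = "ttest")
  expect_true(all(tt$method == "welch_t"))
  # the generated strata differ in location, and medial > intimal densities
  expect_lt(pw$p[pw$stratum_a == "intimal" & pw$stratum_b == "medial"], 1e-6)
})
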