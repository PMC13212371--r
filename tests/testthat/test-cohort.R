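# Cohort simulator: covariate marginals, the proportional-odds generative
# model, the Gaussian-copula density-volume pairs, and reproducibility.

test_that("binary covariates hit their marginal prevalences at large n", {
  cov <- simulate_covariates(n = 1e5, seed = 1)
  expect_lt(abs(mean(cov$hypertension) - 0.742), 0.005)
  expect_lt(abs(mean(cov$female) - 0.519), 0.005)
  expect_lt(abs(mean(cov$diabetes) - 0.112), 0.005)
  spec <- default_covariate_spec()
  spec$hypertension$prevalence <- 0
  z <- simulate_covariates(spec, 1000, seed = 2)
  expect_true(all(z$hypertension == 0))
})

test_that("truncated-normal age matches its analytic moments and respects the
          entry age", {
  cov <- simulate_covariates(n = 1e5, seed = 3)
  expect_true(all(cov$age >= 55))
  # analytic mean/sd of N(69.7, 6.8) truncated at 55
  a <- (55 - 69.7) / 6.8
  lam <- dnorm(a) / (1 - pnorm(a))
  m <- 69.7 + 6.8 * lam
  v <- 6.8^2 * (1 + a * lam - lam^2)
  expect_lt(abs(mean(cov$age) - m), 0.07)
  expect_lt(abs(sd(cov$age) - sqrt(v)), 0.07)
})

test_that("invalid covariate specs are rejected", {
  spec <- default_covariate_spec()
  spec$female$prevalence <- 1.2
  expect_error(simulate_covariates(spec, 10), "prevalence")
  spec2 <- default_covariate_spec()
  spec2$age$sd <- -1
  expect_error(simulate_covariates(spec2, 10), "sd > 0")
})

test_that("with null effects the category distribution matches the cutpoints
          in total variation", {
  eff <- effect_spec(c(female = 0), cutpoints = qlogis(cumsum(
    c(0.16, 0.20, 0.16, 0.16, 0.12, 0.09))))
  cov <- simulate_covariates(n = 1e5, seed = 5)
  y <- simulate_ordinal_outcome(cov, eff, seed = 6)
  target <- po_category_probs(eff, 0)
  emp <- tabulate(y, 7) / 1e5
  expect_lt(sum(abs(emp - target)) / 2, 0.01)
})

test_that("a single binary effect of ln 2 with two categories reproduces the
          closed-form 2x2 odds ratio", {
  eff <- effect_spec(c(female = log(2)), cutpoints = 0.3)
  cov <- simulate_covariates(n = 2e5, seed = 7)
  y <- simulate_ordinal_outcome(cov, eff, seed = 8)
  tab <- matrix(as.numeric(table(cov$female, y)), 2,
                dimnames = list(c("0", "1"), c("1", "2")))
  # odds of the HIGHER category in exposed vs unexposed
  or <- (tab["1", "2"] * tab["0", "1"]) / (tab["1", "1"] * tab["0", "2"])
  expect_lt(abs(or - 2), 0.06)
})

test_that("the copula inversion lands the sample Spearman on its target", {
  for (rho in c(0.2, 0.5, 0.67, 0.9)) {
    pr <- simulate_density_volume_pairs(5e5, rho, seed = round(100 * rho))
    got <- cor(rank(pr$ln_density), rank(pr$ln_volume_plus1))
    expect_lt(abs(got - rho), 0.005)
  }
  pr0 <- simulate_density_volume_pairs(4e4, 0, seed = 10)
  expect_lt(abs(cor(rank(pr0$ln_density), rank(pr0$ln_volume_plus1))),
            2 / sqrt(4e4))
  expect_error(simulate_density_volume_pairs(100, 1), "\\|rho\\| < 1")
  expect_error(simulate_density_volume_pairs(100, -1.2), "\\|rho\\| < 1")
})

test_that("pair margins reproduce the documented medians on the natural
          scale", {
  pr <- simulate_density_volume_pairs(2e5, 0.67, seed = 11)
  expect_lt(abs(median(exp(pr$ln_density)) / 232 - 1), 0.01)
  expect_lt(abs(median(exp(pr$ln_volume_plus1)) / 68 - 1), 0.02)
})

test_that("a fixed master seed reproduces the cohort table bit-identically
          and substreams differ", {
  c1 <- simulate_cohort(n = 400, seed = 42)
  c2 <- simulate_cohort(n = 400, seed = 42)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(n = 400, seed = 43)
  expect_false(identical(c1$density_category, c3$density_category))
  expect_true(all(c1$density_category %in% 1:7))
  expect_false(anyNA(as.data.frame(c1)))
  gen <- attr(c1, "generator")
  expect_identical(gen$master_seed, 42L)
  expect_identical(length(gen$cutpoints), 6L)
})

test_that("default cutpoints keep every generated category populated", {
  co <- simulate_cohort(n = 2040, seed = 9)
  expect_identical(sort(unique(co$density_category)), 1:7)
  expect_true(all(tabulate(co$density_category, 7) / 2040 >= 0.02))
})
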