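# Parameter-recovery experiments: simulate cohorts with known generating
# coefficients, refit with the package's own estimators, and summarize how
# well the generating values are recovered.  These loops are the package's
# evidence that the inference chain is implemented correctly -- the real
# cohort's data cannot be redistributed, so correctness is demonstrated on
# synthetic cohorts whose truths are the published effect sizes.

# population variance of a normal truncated below at `lower`
truncnorm_var <- function(sd, mean = 0, lower = -Inf) {
  if (!is.finite(lower)) return(sd^2)
  a <- (lower - mean) / sd
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  sd^2 * (1 + a * lam - lam^2)
}

#' Default generating coefficients for the linear density model
#'
#' Coefficients on the standardized ln average-density outcome ("per SD
#' increase"): age 0.02 per year, female -0.26, ever smoking 0.17, obesity
#' 0.03, hypertension 0.21, diabetes 0.18, non-HDL cholesterol 0.08 per
#' mmol/L, lipid-lowering medication 0.23, CHD history 0.51, CVA history
#' 0.13, 64-slice scanner -0.08.
#'
#' @return Named numeric vector of coefficients.
#' @export
default_linear_effects <- function() {
  c(age = 0.02, female = -0.26, ever_smoking = 0.17, obesity = 0.03,
    hypertension = 0.21, diabetes = 0.18, non_hdl_chol = 0.08,
    lipid_lowering = 0.23, chd_history = 0.51, cva_history = 0.13,
    scanner_64slice = -0.08)
}

#' Simulate a standardized continuous log-outcome
#'
#' `y = X beta + e`, with normal noise scaled so the population variance of
#' the outcome is 1 (the covariate-explained variance is computed
#' analytically from the marginals under independence). Coefficients are
#' then directly interpretable on the "per SD of the outcome" scale.
#'
#' @param covariates covariate table containing every column of `beta`.
#' @param beta named generating coefficients.
#' @param seed integer seed.
#' @param cov_spec covariate spec used for the analytic variance; defaults
#'   to [default_covariate_spec()].
#' @return Numeric outcome vector with (population) unit variance.
#' @export
simulate_linear_outcome <- function(covariates, beta = default_linear_effects(),
                                    seed = 1L,
                                    cov_spec = default_covariate_spec()) {
  miss <- setdiff(names(beta), names(covariates))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
  vars <- vapply(names(beta), function(nm) {
    cv <- cov_spec[[nm]]
    if (is.null(cv)) stop("covariate '", nm, "' missing from spec")
    if (cv$kind == "binary") cv$prevalence * (1 - cv$prevalence)
    else truncnorm_var(cv$sd, cv$mean, if (is.null(cv$lower)) -Inf else cv$lower)
  }, numeric(1))
  explained <- sum(beta^2 * vars)
  if (explained >= 1)
    stop("generating coefficients explain >= 100% of a unit-variance outcome")
  X <- as.matrix(covariates[names(beta)])
  set.seed(as.integer(seed))
  drop(X %*% beta) + stats::rnorm(nrow(X), sd = sqrt(1 - explained))
}

#' Ordinal parameter-recovery experiment
#'
#' Repeatedly simulates cohorts under the proportional-odds generative model
#' and refits them with [fit_proportional_odds()]. Reports, per covariate,
#' the generating odds ratio, the mean fitted odds ratio across seeds, and
#' (optionally) empirical 95% Wald CI coverage of the generating log-odds.
#'
#' @param n cohort size per replicate (default 2040).
#' @param n_seeds number of simulate-refit replicates.
#' @param seed master seed; replicate r uses substream `seed + r`.
#' @param cov_spec,effects generating specs.
#' @param coverage if `TRUE`, also record whether each replicate's CI covers
#'   the generating value.
#' @return List: `or_estimates` (n_seeds x p matrix of fitted ORs),
#'   `or_mean`, `or_true`, `coverage` (per-covariate proportion, or NULL),
#'   `n`, `n_seeds`, `converged` (logical per replicate).
#' @export
recover_ordinal_ors <- function(n = 2040, n_seeds = 20, seed = 1L,
                                cov_spec = default_covariate_spec(),
                                effects = default_effect_spec(cov_spec = cov_spec),
                                coverage = FALSE) {
  p <- length(effects$beta)
  ors <- matrix(NA_real_, n_seeds, p, dimnames = list(NULL, names(effects$beta)))
  cover <- matrix(NA, n_seeds, p, dimnames = list(NULL, names(effects$beta)))
  conv <- logical(n_seeds)
  for (r in seq_len(n_seeds)) {
    s <- substream_seed(seed, r)
    cov <- simulate_covariates(cov_spec, n, seed = s)
    y <- simulate_ordinal_outcome(cov, effects, seed = substream_seed(s, 1))
    fit <- fit_proportional_odds(cov[names(effects$beta)], y)
    ors[r, ] <- fit$or
    conv[r] <- fit$converged
    if (coverage) {
      lo <- fit$coefficients - 1.96 * fit$se
      hi <- fit$coefficients + 1.96 * fit$se
      cover[r, ] <- effects$beta >= lo & effects$beta <= hi
    }
  }
  list(or_estimates = ors, or_mean = colMeans(ors), or_true = exp(effects$beta),
       coverage = if (coverage) colMeans(cover) else NULL,
       n = n, n_seeds = n_seeds, converged = conv)
}

#' Spearman recovery experiment
#'
#' Simulates copula-linked pairs at the target rank correlation and measures
#' the sample Spearman coefficient per seed.
#'
#' @param n pairs per replicate.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @param target_spearman generating population rank correlation.
#' @return List: `rho_estimates`, `rho_mean`, `target`, `n`, `n_seeds`.
#' @export
recover_spearman <- function(n = 2040, n_seeds = 50, seed = 1L,
                             target_spearman = 0.67) {
  rhos <- vapply(seq_len(n_seeds), function(r) {
    pr <- simulate_density_volume_pairs(n, target_spearman,
                                        seed = substream_seed(seed, r))
    stats::cor(rank(pr$ln_density), rank(pr$ln_volume_plus1))
  }, numeric(1))
  list(rho_estimates = rhos, rho_mean = mean(rhos), target = target_spearman,
       n = n, n_seeds = n_seeds)
}

#' Linear parameter-recovery experiment
#'
#' Simulates unit-variance log-outcomes with known coefficients and refits
#' with [fit_linear_standardized()].
#'
#' @param n cohort size per replicate.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @param cov_spec covariate spec.
#' @param beta generating coefficients.
#' @param coverage if `TRUE`, record per-covariate 95% CI coverage.
#' @return List: `beta_estimates` (n_seeds x p), `beta_mean`, `beta_true`,
#'   `coverage` (or NULL), `n`, `n_seeds`.
#' @export
recover_linear_betas <- function(n = 2040, n_seeds = 20, seed = 1L,
                                 cov_spec = default_covariate_spec(),
                                 beta = default_linear_effects(),
                                 coverage = FALSE) {
  p <- length(beta)
  est <- matrix(NA_real_, n_seeds, p, dimnames = list(NULL, names(beta)))
  cover <- matrix(NA, n_seeds, p, dimnames = list(NULL, names(beta)))
  for (r in seq_len(n_seeds)) {
    s <- substream_seed(seed, r)
    cov <- simulate_covariates(cov_spec, n, seed = s)
    y <- simulate_linear_outcome(cov, beta, seed = substream_seed(s, 1),
                                 cov_spec = cov_spec)
    fit <- fit_linear_standardized(cov[names(beta)], y)
    est[r, ] <- fit$coefficients
    if (coverage)
      cover[r, ] <- beta >= fit$ci[, "lower"] & beta <= fit$ci[, "upper"]
  }
  list(beta_estimates = est, beta_mean = colMeans(est), beta_true = beta,
       coverage = if (coverage) colMeans(cover) else NULL,
       n = n, n_seeds = n_seeds)
}
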