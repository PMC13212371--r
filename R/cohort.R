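# Synthetic cohort generator: covariates drawn from published population
# marginals, a 7-level ordinal density outcome generated under a
# proportional-odds model, copula-linked ln-density / ln-volume pairs, and
# artery-level subtype scores with density distributions.  This is the
# testbed for the inference chain: parameters going in are known exactly, so
# estimator recovery can be checked.
#
# Covariates are drawn independently -- a documented simplification (the
# joint distribution of real risk factors is not published), adequate for
# parameter-recovery testing though not for emulating real confounding.

# deterministic substream derivation from one master seed (Lehmer step),
# kept below 2^31 - 1 so it stays a valid R integer seed
substream_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}

#' Default covariate marginals
#'
#' Marginal distributions of the modelled cardiovascular covariates in an
#' older general population: age 69.7 (SD 6.8) years truncated at 55 (the
#' cohort entry criterion), female 51.9%, ever smoking 69.7%, obesity 24.1%,
#' hypertension 74.2%, diabetes 11.2%, serum non-HDL cholesterol 4.2 (SD
#' 1.0) mmol/L, lipid-lowering medication 24.4%, CHD history 9.2%, CVA
#' history 6.3%, and 64-slice scanner for 1691 of 2464 scans.
#'
#' @return A `covariate_spec`: named list of per-covariate marginal
#'   descriptors (`kind`, and `prevalence` or `mean`/`sd`/`lower`).
#' @export
default_covariate_spec <- function() {
  structure(list(
    age             = list(kind = "continuous", mean = 69.7, sd = 6.8, lower = 55),
    female          = list(kind = "binary", prevalence = 0.519),
    ever_smoking    = list(kind = "binary", prevalence = 0.697),
    obesity         = list(kind = "binary", prevalence = 0.241),
    hypertension    = list(kind = "binary", prevalence = 0.742),
    diabetes        = list(kind = "binary", prevalence = 0.112),
    non_hdl_chol    = list(kind = "continuous", mean = 4.2, sd = 1.0, lower = 0.5),
    lipid_lowering  = list(kind = "binary", prevalence = 0.244),
    chd_history     = list(kind = "binary", prevalence = 0.092),
    cva_history     = list(kind = "binary", prevalence = 0.063),
    scanner_64slice = list(kind = "binary", prevalence = 1691 / 2464)
  ), class = "covariate_spec")
}

validate_covariate_spec <- function(spec) {
  if (!is.list(spec) || is.null(names(spec)) || any(names(spec) == ""))
    stop("covariate spec must be a named list")
  for (nm in names(spec)) {
    cv <- spec[[nm]]
    if (is.null(cv$kind) || !cv$kind %in% c("binary", "continuous"))
      stop(sprintf("covariate '%s': kind must be binary or continuous", nm))
    if (cv$kind == "binary") {
      if (is.null(cv$prevalence) || cv$prevalence < 0 || cv$prevalence > 1)
        stop(sprintf("covariate '%s': prevalence must lie in [0, 1]", nm))
    } else {
      if (is.null(cv$mean) || is.null(cv$sd) || cv$sd <= 0)
        stop(sprintf("covariate '%s': continuous marginal needs mean and sd > 0", nm))
    }
  }
  invisible(spec)
}

# mean of a normal truncated below at `lower`
truncnorm_mean <- function(mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(mean)
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Simulate a covariate table
#'
#' Independent draws per covariate: binaries as Bernoulli at the stated
#' prevalence, continuous covariates as (optionally left-truncated) normals
#' drawn by inverse-CDF so a fixed seed gives bit-identical output.
#'
#' @param spec a covariate spec, see [default_covariate_spec()].
#' @param n number of participants.
#' @param seed integer seed.
#' @return `data.frame` with `participant_id` and one column per covariate.
#' @export
simulate_covariates <- function(spec = default_covariate_spec(), n, seed = 1L) {
  validate_covariate_spec(spec)
  if (n < 1) stop("`n` must be at least 1")
  set.seed(as.integer(seed))
  out <- data.frame(participant_id = seq_len(n))
  for (nm in names(spec)) {
    cv <- spec[[nm]]
    if (cv$kind == "binary") {
      out[[nm]] <- stats::rbinom(n, 1L, cv$prevalence)
    } else {
      lower <- if (is.null(cv$lower)) -Inf else cv$lower
      p0 <- stats::pnorm(lower, cv$mean, cv$sd)
      u <- stats::runif(n, p0, 1)
      out[[nm]] <- stats::qnorm(u, cv$mean, cv$sd)
    }
  }
  out
}

#' Default generating effects for the ordinal density outcome
#'
#' Coefficients on the latent logistic scale are the natural logs of the
#' adjusted common odds ratios reported for determinants of calcification
#' density: age 1.07 per year, female sex 0.65, ever smoking 1.35, obesity
#' 1.16, hypertension 1.59, diabetes 1.40, non-HDL cholesterol 1.14 per
#' mmol/L, lipid-lowering medication 1.58, CHD history 2.59, CVA history
#' 1.56, 64-slice scanner 0.94.
#'
#' @param cutpoints optional 6 increasing latent cutpoints; when `NULL` they
#'   are derived by [default_cutpoints()] so the implied 7-category
#'   distribution is non-degenerate.
#' @param cov_spec covariate spec used when deriving default cutpoints.
#' @return An `effect_spec`: list with `beta` (named numeric) and
#'   `cutpoints` (numeric, length K-1).
#' @export
default_effect_spec <- function(cutpoints = NULL,
                                cov_spec = default_covariate_spec()) {
  beta <- log(c(age = 1.07, female = 0.65, ever_smoking = 1.35,
                obesity = 1.16, hypertension = 1.59, diabetes = 1.40,
                non_hdl_chol = 1.14, lipid_lowering = 1.58,
                chd_history = 2.59, cva_history = 1.56,
                scanner_64slice = 0.94))
  if (is.null(cutpoints)) cutpoints <- default_cutpoints(beta, cov_spec)
  effect_spec(beta, cutpoints)
}

#' Construct an effect spec
#'
#' @param beta named numeric coefficients (log common odds ratios).
#' @param cutpoints strictly increasing latent cutpoints (length K-1 for a
#'   K-category outcome).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(beta, cutpoints) {
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("`beta` must be a named numeric vector")
  if (any(!is.finite(beta))) stop("coefficients must be finite")
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1L || any(diff(cutpoints) <= 0))
    stop("`cutpoints` must be strictly increasing")
  structure(list(beta = beta, cutpoints = cutpoints), class = "effect_spec")
}

#' Derive cutpoints from target marginal category probabilities
#'
#' Centers the latent scale on the mean linear predictor implied by the
#' covariate marginals (using the truncated-normal mean for truncated
#' continuous covariates), then places cutpoints at the logistic quantiles
#' of the cumulative target probabilities. With the default targets every
#' category keeps at least 2% mass, so parameter-recovery fits never face a
#' near-empty category.
#'
#' @param beta named coefficient vector.
#' @param cov_spec covariate spec supplying the marginal means.
#' @param target_probs length-K probabilities, summing to 1.
#' @return Numeric cutpoints of length K-1.
#' @export
default_cutpoints <- function(beta, cov_spec = default_covariate_spec(),
                              target_probs = c(0.16, 0.20, 0.16, 0.16,
                                               0.12, 0.09, 0.11)) {
  if (abs(sum(target_probs) - 1) > 1e-8)
    stop("`target_probs` must sum to 1")
  if (any(target_probs <= 0)) stop("`target_probs` must be positive")
  mu <- vapply(names(beta), function(nm) {
    cv <- cov_spec[[nm]]
    if (is.null(cv)) stop(sprintf("covariate '%s' missing from spec", nm))
    if (cv$kind == "binary") cv$prevalence
    else truncnorm_mean(cv$mean, cv$sd,
                        if (is.null(cv$lower)) -Inf else cv$lower)
  }, numeric(1))
  m <- sum(beta * mu)
  k <- length(target_probs)
  m + stats::qlogis(cumsum(target_probs)[-k])
}

#' Simulate the ordinal density outcome
#'
#' Generates a latent variable `u = X beta + e` with standard-logistic noise
#' and cuts it at the spec cutpoints, so that
#' `P(Y <= k | x) = plogis(alpha_k - x' beta)` exactly -- the generative
#' twin of the proportional-odds model fitted downstream.
#'
#' @param covariates `data.frame` containing every column named in
#'   `effects$beta`.
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return Integer vector of categories in `1..K`.
#' @export
simulate_ordinal_outcome <- function(covariates, effects, seed = 1L) {
  if (!inherits(effects, "effect_spec")) stop("`effects` must be an effect_spec")
  miss <- setdiff(names(effects$beta), names(covariates))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(covariates[names(effects$beta)])
  set.seed(as.integer(seed))
  u <- drop(X %*% effects$beta) + stats::rlogis(nrow(X))
  1L + findInterval(u, effects$cutpoints, left.open = TRUE)
}

#' Simulate correlated ln-density / ln-volume pairs
#'
#' A Gaussian copula with Pearson parameter `r = 2 sin(pi * rho_S / 6)` --
#' the exact inversion of the bivariate-normal rank correlation -- feeds two
#' normal margins on the log scale, so the pair's population Spearman
#' correlation equals the requested target while each exponentiated margin
#' is right-skewed log-normal, as calcification volume and density are.
#' Default margins reproduce a median density of 232 HU (IQR 189-287) and a
#' median volume of 67 mm^3 (IQR 22-189, with the +1 mm^3 offset).
#'
#' @param n number of pairs.
#' @param target_spearman population Spearman correlation, `|rho| < 1`.
#' @param seed integer seed.
#' @param density_meanlog,density_sdlog,volume_meanlog,volume_sdlog normal
#'   parameters of the two log-scale margins.
#' @return `data.frame` with columns `ln_density` and `ln_volume_plus1`.
#' @export
simulate_density_volume_pairs <- function(n, target_spearman = 0.67, seed = 1L,
                                          density_meanlog = log(232),
                                          density_sdlog = lognormal_sdlog(189, 287),
                                          volume_meanlog = log(67 + 1),
                                          volume_sdlog = lognormal_sdlog(23, 190)) {
  if (!is.finite(target_spearman) || abs(target_spearman) >= 1)
    stop("`target_spearman` must satisfy |rho| < 1")
  r <- 2 * sin(pi * target_spearman / 6)
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  data.frame(ln_density = density_meanlog + density_sdlog * z1,
             ln_volume_plus1 = volume_meanlog + volume_sdlog * z2)
}

#' Log-normal sigma matched to an interquartile range
#'
#' For a log-normal variable, `log(q3) - log(q1) = 2 * qnorm(0.75) * sdlog`;
#' inverting gives the sigma whose quartile ratio matches the observed IQR.
#'
#' @param q1,q3 first and third quartiles (natural scale, both > 0).
#' @return `sdlog` of the matching log-normal.
#' @export
lognormal_sdlog <- function(q1, q3) {
  if (q1 <= 0 || q3 <= q1) stop("need 0 < q1 < q3")
  log(q3 / q1) / (2 * stats::qnorm(0.75))
}

#' Simulate artery-level subtype scores and densities
#'
#' Draws a subtype per artery from the mixture weights, a Kockelkoren score
#' uniformly within that subtype's score range (0-4 / 5-8 / 9-19), and a
#' mean density from a log-normal whose median and IQR-matched sigma are set
#' per subtype. Defaults follow the artery-level subtype mix (20.5% intimal,
#' 56.6% ambiguous, 23.0% medial, renormalized) and the subtype density
#' medians 210 (179-264), 255 (198-310) and 294 (230-351) HU.
#'
#' @param n_arteries number of arteries.
#' @param weights mixture weights for (intimal, ambiguous, medial); must sum
#'   to 1.
#' @param medians per-subtype density medians (HU).
#' @param iqrs list of three `c(q1, q3)` pairs.
#' @param seed integer seed.
#' @return `data.frame`: `artery`, `kockelkoren_score`, `mean_hu`,
#'   `subtype_true`.
#' @export
simulate_subtype_arteries <- function(n_arteries,
                                      weights = c(0.205, 0.566, 0.230) / 1.001,
                                      medians = c(210, 255, 294),
                                      iqrs = list(c(179, 264), c(198, 310),
                                                  c(230, 351)),
                                      seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-6) stop("`weights` must sum to 1")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  set.seed(as.integer(seed))
  ranges <- list(intimal = 0:4, ambiguous = 5:8, medial = 9:19)
  subtype <- sample(SUBTYPE_LABELS, n_arteries, replace = TRUE, prob = weights)
  score <- vapply(subtype, function(s) sample(ranges[[s]], 1L), integer(1))
  idx <- match(subtype, SUBTYPE_LABELS)
  sdlogs <- vapply(iqrs, function(q) lognormal_sdlog(q[1], q[2]), numeric(1))
  dens <- stats::rlnorm(n_arteries, meanlog = log(medians)[idx],
                        sdlog = sdlogs[idx])
  data.frame(artery = seq_len(n_arteries), kockelkoren_score = score,
             mean_hu = dens,
             subtype_true = factor(subtype, levels = SUBTYPE_LABELS))
}

#' Simulate a complete cohort table
#'
#' One master seed spawns independent substreams for covariates, the ordinal
#' outcome, the density-volume pairs, and the per-carotid subtype scores, so
#' each component is reproducible on its own and the whole table is
#' bit-identical under a fixed seed. The table is complete by construction
#' (no missingness is simulated).
#'
#' @param n cohort size; the default 2040 matches the size of the analysis
#'   set with detectable calcification.
#' @param seed master seed.
#' @param cov_spec covariate spec.
#' @param effects effect spec for the ordinal outcome.
#' @param target_spearman population rank correlation between the log
#'   density and log volume columns.
#' @return `data.frame` (`cohort_table`): participant id, covariates,
#'   `density_category`, `ln_density`, `ln_volume_plus1`, and Kockelkoren
#'   scores for the two intracranial carotids. The generating parameters
#'   and substream seeds are attached as the `"generator"` attribute.
#' @export
simulate_cohort <- function(n = 2040, seed = 1L,
                            cov_spec = default_covariate_spec(),
                            effects = default_effect_spec(cov_spec = cov_spec),
                            target_spearman = 0.67) {
  seeds <- vapply(1:4, function(k) substream_seed(seed, k), integer(1))
  cov <- simulate_covariates(cov_spec, n, seed = seeds[1])
  y <- simulate_ordinal_outcome(cov, effects, seed = seeds[2])
  pairs <- simulate_density_volume_pairs(n, target_spearman, seed = seeds[3])
  set.seed(seeds[4])
  sc_l <- sample(0:19, n, replace = TRUE)
  sc_r <- sample(0:19, n, replace = TRUE)
  out <- cbind(cov, density_category = y, pairs,
               kockelkoren_ICA_left = sc_l, kockelkoren_ICA_right = sc_r)
  attr(out, "generator") <- list(master_seed = as.integer(seed),
                                 substream_seeds = seeds,
                                 beta = effects$beta,
                                 cutpoints = effects$cutpoints,
                                 target_spearman = target_spearman)
  class(out) <- c("cohort_table", "data.frame")
  out
}
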