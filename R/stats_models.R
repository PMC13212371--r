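# Remaining pieces of the inference chain: rank correlation with a bootstrap
# interval, linear regression on the standardized log outcome, the natural-log
# transform conventions, the sensitivity-analysis restriction, and
# baseline-table descriptives.

#' Spearman correlation with bootstrap confidence interval
#'
#' The coefficient is the Pearson correlation of mid-ranks (ties receive
#' average ranks), and the 95% interval is a seeded percentile bootstrap
#' over participants -- resampling pairs, recomputing rho on each replicate,
#' and taking the 2.5 and 97.5 percentiles. A Fisher-z interval is available
#' as an alternative (`ci = "fisher"`).
#'
#' @param x,y paired numeric samples without missing values, `n >= 10`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap resampling.
#' @param ci `"bootstrap"` (default) or `"fisher"`.
#' @return List: `rho`, `ci_lower`, `ci_upper`, `n`, `n_boot`, `seed`,
#'   `method`. Constant input gives `rho = NA` with `degenerate = TRUE`.
#' @export
spearman_with_ci <- function(x, y, n_boot = 1000L, seed = 1L,
                             ci = c("bootstrap", "fisher")) {
  ci <- match.arg(ci)
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 10) stop("need at least 10 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                n = n, n_boot = 0L, seed = as.integer(seed),
                method = ci, degenerate = TRUE))
  }
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  rho <- rho_of(x, y)
  if (ci == "bootstrap") {
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) == 1L || length(unique(y[idx])) == 1L)
        return(NA_real_)
      rho_of(x[idx], y[idx])
    }, numeric(1))
    qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else {
    z <- atanh(rho)
    hw <- 1.96 / sqrt(n - 3)
    qs <- tanh(c(z - hw, z + hw))
  }
  list(rho = rho, ci_lower = qs[1], ci_upper = qs[2], n = n,
       n_boot = if (ci == "bootstrap") as.integer(n_boot) else 0L,
       seed = as.integer(seed), method = ci, degenerate = FALSE)
}

#' Natural-log transform with the volume offset convention
#'
#' Volumes are logged as `ln(volume + 1 mm^3)` so zero-volume observations
#' stay defined; densities (always >= 130 HU when present) are logged
#' directly with offset 0.
#'
#' @param values numeric vector.
#' @param offset added before logging: 1 for volumes, 0 for densities.
#' @return `log(values + offset)`.
#' @export
ln_transform <- function(values, offset = 0) {
  if (anyNA(values)) stop("missing values are not allowed")
  if (any(values + offset <= 0))
    stop("values must be positive after adding the offset")
  log(values + offset)
}

#' Linear regression on a standardized log outcome
#'
#' The outcome is z-scored so each coefficient reads as SDs of the log
#' outcome per unit of the covariate ("per SD increase"); covariates stay on
#' their natural scale. The solve is QR-based; confidence intervals are
#' classical homoskedastic Wald intervals.
#'
#' @param design `data.frame` or matrix of covariates (no intercept column).
#' @param y continuous outcome (typically already log-transformed).
#' @return A `linear_fit` list: `coefficients` (excluding intercept),
#'   `intercept`, `se`, `ci` (lower/upper), `p_value`, `residual_sd`, `r_squared`,
#'   `n`, `outcome_mean`, `outcome_sd` (the standardization applied).
#' @export
fit_linear_standardized <- function(design, y) {
  X0 <- as.matrix(design)
  storage.mode(X0) <- "double"
  n <- length(y)
  if (nrow(X0) != n) stop("design and outcome lengths differ")
  p <- ncol(X0) + 1L
  if (n <= p) stop("need n > number of parameters")
  mu <- mean(y); sdy <- stats::sd(y)
  if (sdy == 0) stop("outcome is constant; cannot standardize")
  z <- (y - mu) / sdy
  X <- cbind(`(Intercept)` = 1, X0)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, z)
  res <- z - drop(X %*% coef)
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- colnames(X)
  tcrit <- stats::qt(0.975, df)
  tstat <- coef / se
  keep <- setdiff(colnames(X), "(Intercept)")
  structure(list(
    coefficients = coef[keep], intercept = coef[["(Intercept)"]],
    se = se[keep],
    ci = cbind(lower = coef[keep] - tcrit * se[keep],
               upper = coef[keep] + tcrit * se[keep]),
    p_value = 2 * stats::pt(-abs(tstat[keep]), df),
    residual_sd = sqrt(s2),
    r_squared = 1 - sum(res^2) / sum((z - mean(z))^2),
    n = n, outcome_mean = mu, outcome_sd = sdy),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit on standardized ln outcome: n = %d, R^2 = %.3f\n",
              x$n, x$r_squared))
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    ci_low = x$ci[, "lower"], ci_high = x$ci[, "upper"],
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Restrict a cohort for the sensitivity analysis
#'
#' Removes participants with prevalent coronary heart disease, prevalent
#' cerebrovascular accident, or lipid-lowering medication use -- the
#' primary-prevention subset in which determinant associations are
#' re-estimated.
#'
#' @param cohort `data.frame` with columns `chd_history`, `cva_history`,
#'   `lipid_lowering` (0/1).
#' @return The restricted `data.frame`, with attribute `"n_removed"`.
#' @export
restrict_sensitivity <- function(cohort) {
  need <- c("chd_history", "cva_history", "lipid_lowering")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  drop <- cohort$chd_history == 1 | cohort$cva_history == 1 |
    cohort$lipid_lowering == 1
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  attr(out, "generator") <- attr(cohort, "generator")
  out
}

#' Baseline descriptive summary
#'
#' Summaries in the conventional baseline-table formats: mean (SD) for
#' normal continuous variables, median (IQR) for skewed ones, count
#' (percentage) for binaries.
#'
#' @param cohort `data.frame`.
#' @param kinds named character vector mapping column names to one of
#'   `"continuous"`, `"skewed"`, `"binary"`. Columns not named are skipped.
#' @return `data.frame`: variable, kind, and formatted `summary` plus the
#'   numeric components (`stat1`, `stat2`, `stat3`).
#' @export
describe_cohort <- function(cohort, kinds) {
  if (is.null(names(kinds))) stop("`kinds` must be a named vector")
  rows <- lapply(names(kinds), function(nm) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("no column named ", nm)
    kind <- kinds[[nm]]
    switch(kind,
      continuous = {
        m <- mean(v); s <- stats::sd(v)
        data.frame(variable = nm, kind = kind,
                   summary = sprintf("%.1f (%.1f)", m, s),
                   stat1 = m, stat2 = s, stat3 = NA_real_)
      },
      skewed = {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(variable = nm, kind = kind,
                   summary = sprintf("%.0f (%.0f-%.0f)", q[2], q[1], q[3]),
                   stat1 = q[2], stat2 = q[1], stat3 = q[3])
      },
      binary = {
        cnt <- sum(v == 1)
        pct <- 100 * cnt / length(v)
        data.frame(variable = nm, kind = kind,
                   summary = sprintf("%d (%.1f)", cnt, pct),
                   stat1 = cnt, stat2 = pct, stat3 = NA_real_)
      },
      stop("unknown kind '", kind, "' for column ", nm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
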