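# Proportional-odds (cumulative logit) regression by Newton-Raphson.
#
# Model: P(Y <= k | x) = plogis(alpha_k - x' beta), one beta shared across
# cutpoints, so exp(beta) is a "common odds ratio": the odds multiplier for
# being in any HIGHER outcome category per unit of x.
#
# The cutpoints are reparameterized as (alpha_1, log successive gaps) so the
# Newton iteration is unconstrained while the ordering alpha_1 < ... <
# alpha_{K-1} holds by construction.  Gradient and Hessian are analytic;
# step-halving enforces a monotone log-likelihood path; standard errors come
# from the observed information at the optimum.

# log-likelihood pieces for categories y under cutpoints alpha and linear
# predictor eta; alpha_0 = -Inf and alpha_K = +Inf are implicit
po_cell_probs <- function(y, alpha, eta, K) {
  aug <- c(-Inf, alpha, Inf)
  a <- aug[y + 1L] - eta        # upper cut for each obs
  b <- aug[y] - eta             # lower cut
  list(a = a, b = b, p = pmax(stats::plogis(a) - stats::plogis(b), 1e-300))
}

po_loglik <- function(theta, X, y, K) {
  p <- ncol(X)
  alpha <- theta_to_alpha(theta, p, K)
  eta <- if (p > 0) drop(X %*% theta[seq_len(p)]) else numeric(length(y))
  sum(log(po_cell_probs(y, alpha, eta, K)$p))
}

theta_to_alpha <- function(theta, p, K) {
  t <- theta[p + seq_len(K - 1L)]
  if (K == 2L) t else cumsum(c(t[1], exp(t[-1])))
}

alpha_to_theta_tail <- function(alpha) {
  if (length(alpha) == 1L) alpha else c(alpha[1], log(diff(alpha)))
}

# analytic gradient and Hessian in the (beta, alpha) parameterization
po_score_info <- function(X, y, K, beta, alpha) {
  p <- ncol(X)
  n <- length(y)
  eta <- if (p > 0) drop(X %*% beta) else numeric(n)
  cp <- po_cell_probs(y, alpha, eta, K)
  Fa <- stats::plogis(cp$a); Fb <- stats::plogis(cp$b)
  fa <- stats::dlogis(cp$a); fb <- stats::dlogis(cp$b)
  ga <- fa * (1 - 2 * Fa);   gb <- fb * (1 - 2 * Fb)
  pr <- cp$p
  Km1 <- K - 1L

  dl_eta <- -(fa - fb) / pr
  g_beta <- if (p > 0) drop(crossprod(X, dl_eta)) else numeric(0)
  w_bb <- (ga - gb) / pr - ((fa - fb) / pr)^2
  H_bb <- if (p > 0) crossprod(X, X * w_bb) else matrix(0, 0, 0)

  g_alpha <- numeric(Km1)
  H_aa <- matrix(0, Km1, Km1)
  H_ab <- matrix(0, Km1, p)
  for (k in seq_len(Km1)) {
    up <- y == k          # alpha_k is the upper cut
    lo <- y == k + 1L     # alpha_k is the lower cut
    g_alpha[k] <- sum(fa[up] / pr[up]) - sum(fb[lo] / pr[lo])
    H_aa[k, k] <- sum(ga[up] / pr[up] - (fa[up] / pr[up])^2) +
      sum(-gb[lo] / pr[lo] - (fb[lo] / pr[lo])^2)
    if (k < Km1) {
      # obs in category k+1 couple lower cut alpha_k with upper cut alpha_{k+1}
      H_aa[k, k + 1L] <- H_aa[k + 1L, k] <- sum(fa[lo] * fb[lo] / pr[lo]^2)
    }
    if (p > 0) {
      cu <- -ga[up] / pr[up] + fa[up] * (fa[up] - fb[up]) / pr[up]^2
      cl <-  gb[lo] / pr[lo] - fb[lo] * (fa[lo] - fb[lo]) / pr[lo]^2
      H_ab[k, ] <- drop(crossprod(X[up, , drop = FALSE], cu)) +
        drop(crossprod(X[lo, , drop = FALSE], cl))
    }
  }
  list(g_beta = g_beta, g_alpha = g_alpha,
       H_bb = H_bb, H_aa = H_aa, H_ab = H_ab)
}

#' Fit a proportional-odds model
#'
#' Maximum-likelihood cumulative-logit regression,
#' `P(Y <= k | x) = plogis(alpha_k - x' beta)`, fitted by Newton-Raphson
#' with analytic gradient and Hessian, step-halving, and log-gap
#' reparameterized cutpoints (ordering enforced by construction). An odds
#' ratio `exp(beta) > 1` means higher odds of a higher outcome category.
#' Wald 95% confidence intervals use the observed information.
#'
#' @param design `data.frame` or matrix of covariates (no intercept column;
#'   may have zero columns for an intercept-only fit). Constant columns are
#'   rejected since they are inestimable alongside the cutpoints.
#' @param y ordinal outcome: integer codes `1..K` or an ordered factor.
#'   Every category must be observed at least once.
#' @param max_iter maximum Newton iterations (default 100).
#' @param tol convergence tolerance on the gradient sup-norm (default 1e-8).
#' @return An `ordinal_fit` list: `coefficients`, `se`, `or`, `or_ci`
#'   (columns `lower`/`upper`), `cutpoints`, `se_cutpoints`, `vcov` (on the
#'   (beta, alpha) scale), `loglik`, `loglik_trace`, `n`, `K`, `converged`,
#'   `iterations`.
#' @export
fit_proportional_odds <- function(design, y, max_iter = 100L, tol = 1e-8) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (length(y) == 0L) stop("no observations to fit")
  if (anyNA(y)) stop("outcome contains missing values")
  K <- max(y)
  if (min(y) < 1L || K < 2L) stop("outcome must use integer categories 1..K, K >= 2")
  obs <- tabulate(y, K)
  if (any(obs == 0L))
    stop("category ", paste(which(obs == 0L), collapse = ", "),
         " unobserved: collapse categories before fitting")
  if (is.null(design)) design <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(design)
  if (nrow(X) != length(y)) stop("design and outcome lengths differ")
  storage.mode(X) <- "double"
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(col) length(unique(col)) == 1L)
    if (any(const))
      stop("constant column(s) in design: ",
           paste(colnames(X)[const], collapse = ", "))
  }
  p <- ncol(X)
  n <- length(y)

  # start: zero slopes, cutpoints at the logit of the cumulative frequencies
  alpha0 <- stats::qlogis(cumsum(obs / n)[-K])
  theta <- c(numeric(p), alpha_to_theta_tail(alpha0))
  ll <- po_loglik(theta, X, y, K)
  trace <- ll
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    beta <- theta[seq_len(p)]
    alpha <- theta_to_alpha(theta, p, K)
    si <- po_score_info(X, y, K, beta, alpha)

    # chain rule into the (beta, t) parameterization
    Km1 <- K - 1L
    J <- matrix(0, Km1, Km1)
    J[, 1] <- 1
    if (Km1 > 1) {
      tg <- theta[p + 2:Km1]
      for (j in 2:Km1) J[j:Km1, j] <- exp(tg[j - 1L])
    }
    g_t <- drop(crossprod(J, si$g_alpha))
    D <- matrix(0, Km1, Km1)
    if (Km1 > 1)
      for (j in 2:Km1)
        D[j, j] <- exp(theta[p + j]) * sum(si$g_alpha[j:Km1])
    H_tt <- crossprod(J, si$H_aa %*% J) + D
    H_tb <- crossprod(J, si$H_ab)          # (Km1 x p)
    g <- c(si$g_beta, g_t)
    H <- rbind(cbind(si$H_bb, t(H_tb)), cbind(H_tb, H_tt))

    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {                   # ridge fallback for a singular Hessian
      step <- solve(H - diag(1e-6, nrow(H)), g)
    }
    # Newton ascent: theta - H^{-1} g (H is negative definite near optimum)
    lambda <- 1
    improved <- FALSE
    for (h in 1:40) {
      cand <- theta - lambda * step
      llc <- po_loglik(cand, X, y, K)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        theta <- cand
        ll_new <- llc
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    trace <- c(trace, ll_new)
    # convergence judged on the natural-scale gradient
    gnat <- c(si$g_beta, si$g_alpha)
    if (max(abs(gnat)) < tol && abs(ll_new - ll) < 1e-10) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  # final score check (gradient at the accepted theta)
  beta <- theta[seq_len(p)]
  alpha <- theta_to_alpha(theta, p, K)
  si <- po_score_info(X, y, K, beta, alpha)
  if (max(abs(c(si$g_beta, si$g_alpha))) < tol) converged <- TRUE

  info <- -rbind(cbind(si$H_bb, t(si$H_ab)), cbind(si$H_ab, si$H_aa))
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_,
                                                           nrow(info), ncol(info)))
  se_all <- sqrt(pmax(diag(vcov), 0))
  se_beta <- se_all[seq_len(p)]
  se_alpha <- se_all[p + seq_len(K - 1L)]
  nm <- colnames(X)
  if (p > 0 && is.null(nm)) nm <- paste0("x", seq_len(p))
  names(beta) <- nm; names(se_beta) <- nm
  or <- exp(beta)
  or_ci <- cbind(lower = exp(beta - 1.96 * se_beta),
                 upper = exp(beta + 1.96 * se_beta))
  z <- beta / se_beta
  structure(list(coefficients = beta, se = se_beta, or = or, or_ci = or_ci,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 cutpoints = alpha, se_cutpoints = se_alpha, vcov = vcov,
                 loglik = ll, loglik_trace = trace, n = n, K = K,
                 converged = converged, iterations = iter),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: n = %d, K = %d, logLik = %.3f (%s, %d iter)\n",
              x$n, x$K, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (length(x$coefficients)) {
    tab <- data.frame(beta = x$coefficients, se = x$se, OR = x$or,
                      ci_low = x$or_ci[, "lower"], ci_high = x$or_ci[, "upper"],
                      p = x$p_value)
    print(round(tab, 4))
  }
  cat("Cutpoints:", paste(round(x$cutpoints, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Fitted marginal category probabilities of an ordinal fit
#'
#' @param fit an `ordinal_fit`.
#' @param x optional covariate vector; when omitted, probabilities at
#'   `x = 0` (for an intercept-only fit these equal the observed category
#'   frequencies at the MLE).
#' @return Numeric vector of K category probabilities.
#' @export
ordinal_category_probs <- function(fit, x = NULL) {
  eta <- if (is.null(x)) 0 else sum(fit$coefficients * x)
  diff(c(0, stats::plogis(fit$cutpoints - eta), 1))
}

#' Closed-form proportional-odds category probabilities
#'
#' The generative probabilities `P(Y = k | x)` implied by an effect spec,
#' used to compare empirical simulation frequencies with their targets.
#'
#' @param effects an [effect_spec()].
#' @param eta linear predictor value(s) `x' beta`.
#' @return Matrix (length(eta) x K) of category probabilities.
#' @export
po_category_probs <- function(effects, eta) {
  upper <- cbind(stats::plogis(outer(-eta, effects$cutpoints, `+`)), 1)
  lower <- cbind(0, upper[, -ncol(upper), drop = FALSE])
  upper - lower
}
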