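# Kockelkoren-score subtype classification of intracranial carotid
# calcification and the density-by-subtype comparison.  The 0-19 visual
# score distinguishes intimal (atherosclerotic) from medial (internal
# elastic lamina) calcification; scores 5-8 form an explicit "ambiguous"
# stratum where observers often disagree.

SUBTYPE_LABELS <- c("intimal", "ambiguous", "medial")

#' Classify the calcification subtype from a Kockelkoren score
#'
#' Scores below 5 are intimal, 5 through 8 ambiguous, above 8 medial; the
#' three strata partition 0-19 into 5 + 4 + 11 scores.
#'
#' @param score integer vector of Kockelkoren scores, each in 0..19.
#' @return Factor with levels `intimal`, `ambiguous`, `medial`.
#' @export
classify_subtype <- function(score) {
  score <- as.numeric(score)
  if (any(is.na(score)) || any(score != floor(score)))
    stop("Kockelkoren scores must be integers")
  if (any(score < 0 | score > 19))
    stop("Kockelkoren scores must lie in 0..19")
  lab <- ifelse(score < 5, "intimal", ifelse(score <= 8, "ambiguous", "medial"))
  factor(lab, levels = SUBTYPE_LABELS)
}

#' Density summaries per calcification subtype
#'
#' Stratifies artery-level mean densities by subtype and reports n, median
#' and IQR per stratum. Arteries that carry a visual score but no measurable
#' density (no voxel at the floor) are excluded from the summaries and
#' counted separately -- mirroring how scored-but-unmeasurable arteries must
#' be handled in real data.
#'
#' @param arteries `data.frame` with columns `kockelkoren_score` and
#'   `mean_hu` (NA for scored arteries without measurable density).
#' @return List with `summary` (`data.frame`: subtype, n, median_hu, q1_hu,
#'   q3_hu; empty strata have n = 0 and NA quantiles) and `n_excluded`.
#' @export
density_by_subtype <- function(arteries) {
  need <- c("kockelkoren_score", "mean_hu")
  if (!all(need %in% names(arteries)))
    stop("`arteries` must have columns kockelkoren_score and mean_hu")
  subtype <- classify_subtype(arteries$kockelkoren_score)
  excluded <- is.na(arteries$mean_hu)
  smry <- do.call(rbind, lapply(SUBTYPE_LABELS, function(s) {
    x <- arteries$mean_hu[!excluded & subtype == s]
    if (length(x)) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(subtype = s, n = length(x), median_hu = q[2],
                 q1_hu = q[1], q3_hu = q[3])
    } else {
      data.frame(subtype = s, n = 0L, median_hu = NA_real_,
                 q1_hu = NA_real_, q3_hu = NA_real_)
    }
  }))
  smry$subtype <- factor(smry$subtype, levels = SUBTYPE_LABELS)
  rownames(smry) <- NULL
  list(summary = smry, n_excluded = sum(excluded))
}

#' Two-sided rank-sum test
#'
#' Mann-Whitney U with the exact null distribution when the smaller sample
#' has at most 8 observations and the pooled data carry no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#' The exact/approximate switch at n = 8 keeps exact enumeration trivially
#' cheap while the approximation is already accurate beyond it.
#'
#' @param x,y non-empty numeric samples.
#' @return List with `statistic` (U, for `x` relative to `y`), `p_value`,
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Pairwise density comparisons across subtypes
#'
#' Runs the two-sided rank-sum test (or, as a flagged alternative, Welch's
#' t-test) on every pair of subtype strata. Raw p-values are the primary
#' output; a Bonferroni-adjusted column is available on request since no
#' adjustment is applied by default for the three display comparisons.
#'
#' @param arteries as in [density_by_subtype()].
#' @param test `"wilcoxon"` (default) or `"ttest"` (Welch).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return `data.frame`: stratum_a, stratum_b, n_a, n_b, statistic, p,
#'   p_adjusted (only when `adjust != "none"`), method.
#' @export
pairwise_subtype_tests <- function(arteries, test = c("wilcoxon", "ttest"),
                                   adjust = c("none", "bonferroni")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  subtype <- classify_subtype(arteries$kockelkoren_score)
  keep <- !is.na(arteries$mean_hu)
  dens <- split(arteries$mean_hu[keep], subtype[keep])
  pairs <- utils::combn(SUBTYPE_LABELS, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    xa <- dens[[a]]; xb <- dens[[b]]
    if (length(xa) == 0L || length(xb) == 0L) {
      return(data.frame(stratum_a = a, stratum_b = b, n_a = length(xa),
                        n_b = length(xb), statistic = NA_real_, p = NA_real_,
                        method = NA_character_))
    }
    if (test == "wilcoxon") {
      r <- wilcoxon_rank_sum(xa, xb)
      data.frame(stratum_a = a, stratum_b = b, n_a = length(xa),
                 n_b = length(xb), statistic = r$statistic, p = r$p_value,
                 method = paste0("wilcoxon_", r$method))
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      data.frame(stratum_a = a, stratum_b = b, n_a = length(xa),
                 n_b = length(xb), statistic = unname(tt$statistic),
                 p = tt$p.value, method = "welch_t")
    }
  }))
  if (adjust == "bonferroni")
    out$p_adjusted <- pmin(1, out$p * sum(!is.na(out$p)))
  rownames(out) <- NULL
  out
}
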