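#' Bland-Altman agreement analysis of repeated measurements
#'
#' Differences are `value_1 - value_2`; the 95% limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation. The
#' 95% confidence interval of the mean difference is also reported, since
#' the two are easily conflated.
#'
#' @param pairs data frame with columns `value_1` and `value_2` (one row per
#'   subject), or a numeric vector for `value_1` with `value_2` given.
#' @param value_2 second measurements when `pairs` is a vector.
#' @return List with `mean_difference`, `sd_difference`, `loa`
#'   (lower/upper limits of agreement), `ci_mean` and `n`.
#' @export
bland_altman <- function(pairs, value_2 = NULL) {
  if (is.data.frame(pairs)) {
    v1 <- pairs$value_1; v2 <- pairs$value_2
  } else {
    v1 <- pairs; v2 <- value_2
  }
  stopifnot(length(v1) == length(v2), all(is.finite(v1)), all(is.finite(v2)))
  if (length(v1) < 3) stop("at least 3 pairs required")
  d <- v1 - v2
  md <- mean(d)
  s <- sd(d)
  list(mean_difference = md, sd_difference = s,
       loa = c(lower = md - 1.96 * s, upper = md + 1.96 * s),
       ci_mean = c(lower = md - 1.96 * s / sqrt(length(d)),
                   upper = md + 1.96 * s / sqrt(length(d))),
       n = length(d))
}

#' Coefficient of variation of repeated measurements
#'
#' Per subject, `CoV = sd(value_1, value_2) / |mean| * 100` with the n-1
#' standard deviation (for a pair, `sd = |difference| / sqrt(2)`). Subjects
#' with zero mean are excluded with a warning. The group summary is the
#' median CoV.
#'
#' @param pairs data frame with columns `subject_id`, `value_1`, `value_2`.
#' @return List with per-subject data frame `cov` and `median_cov`.
#' @export
coefficient_of_variation <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("value_1", "value_2") %in% names(pairs)))
  sid <- if ("subject_id" %in% names(pairs)) pairs$subject_id
         else seq_len(nrow(pairs))
  m <- (pairs$value_1 + pairs$value_2) / 2
  s <- abs(pairs$value_1 - pairs$value_2) / sqrt(2)
  zero <- m == 0
  if (any(zero)) warning(sum(zero), " subject(s) excluded: zero mean")
  cov <- data.frame(subject_id = sid[!zero],
                    cov_pct = 100 * s[!zero] / abs(m[!zero]))
  list(cov = cov, median_cov = median(cov$cov_pct))
}

#' Group-comparison and correlation reporting helper
#'
#' Thin wrapper over the standard nonparametric routines used when comparing
#' metric distributions between participant groups: a Kruskal-Wallis test
#' with pairwise Wilcoxon post hoc comparisons (Holm-adjusted), and Spearman
#' correlation against a covariate when `covariate` is given.
#'
#' @param values numeric metric values.
#' @param groups factor of group labels (same length).
#' @param covariate optional numeric covariate for Spearman correlation.
#' @return List with `kruskal` (htest), `pairwise` (pairwise.htest) and,
#'   when requested, `spearman` (htest).
#' @export
group_tests <- function(values, groups, covariate = NULL) {
  groups <- factor(groups)
  out <- list(kruskal = kruskal.test(values, groups),
              pairwise = pairwise.wilcox.test(values, groups,
                                              p.adjust.method = "holm",
                                              exact = FALSE))
  if (!is.null(covariate))
    out$spearman <- suppressWarnings(
      cor.test(values, covariate, method = "spearman"))
  out
}
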