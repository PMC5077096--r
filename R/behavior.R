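# Behavioral analysis: network-strength-to-score regressions and group
# comparisons recomputed from published summary statistics.

#' Reference behavioral and demographic summary statistics
#'
#' Group means, standard deviations, sample sizes (50 per group), and the
#' published t statistics for the demographic and behavioral scales of the
#' reference cohort (substance dependent individuals vs healthy controls):
#' age, education, the behavioral inhibition/activation scales (BIS, BAS and
#' BAS subscales), the Barratt impulsiveness scale (BIS-11 and subscales),
#' and PANAS-X positive/negative affect.
#'
#' @param demographics If `TRUE` include the age and education rows along
#'   with the behavioral scales (default `TRUE`).
#' @return Data frame with columns `scale`, `mean_sdi`, `sd_sdi`,
#'   `mean_control`, `sd_control`, `n_sdi`, `n_control`, `t_published`.
#' @export
behavior_reference <- function(demographics = FALSE) {
  ref <- data.frame(
    scale = c("Age", "Education",
              "BIS", "BAS", "Drive", "Fun Seeking", "Reward",
              "BIS-11", "Motor", "Non-Planning", "Attentional",
              "Positive Affect", "Negative Affect"),
    mean_sdi = c(34.18, 12.48, 20.64, 76.74, 12.80, 13.16, 17.40,
                 72.16, 27.30, 27.08, 17.78, 35.32, 21.54),
    sd_sdi = c(7.63, 1.42, 3.26, 6.54, 2.17, 1.85, 1.94,
               11.54, 4.72, 4.96, 3.81, 6.09, 7.98),
    mean_control = c(31.60, 14.66, 20.10, 69.40, 10.34, 11.38, 17.10,
                     57.30, 22.78, 20.48, 14.04, 35.92, 14.72),
    sd_control = c(8.57, 1.47, 3.56, 9.27, 2.26, 2.18, 1.75,
                   6.71, 3.02, 3.33, 3.14, 6.09, 3.48),
    n_sdi = 50L, n_control = 50L,
    t_published = c(1.589, -7.560, 0.792, 4.575, 5.551, 4.414, 0.812,
                    7.871, 5.707, 7.809, 5.361, -0.488, 5.540),
    stringsAsFactors = FALSE
  )
  if (!demographics) ref <- ref[!ref$scale %in% c("Age", "Education"), ]
  rownames(ref) <- NULL
  ref
}

#' Welch t-test from group summary statistics
#'
#' Recomputes a two-sample t statistic from per-group mean, SD and n:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with the Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. With equal group sizes the
#' statistic coincides with the pooled-variance t.
#'
#' @param mean1,sd1,n1 First group summary (by convention the SDI group).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `dof`, `p`.
#' @export
#' @examples
#' ttest_from_summary(76.74, 6.54, 50, 69.40, 9.27, 50)$t  # ~4.575
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("SDs must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  dof <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t_stat, dof = dof,
       p = 2 * stats::pt(-abs(t_stat), df = dof))
}

#' Recompute the reference group comparisons from summary statistics
#'
#' Applies [ttest_from_summary()] to every row of [behavior_reference()].
#'
#' @inheritParams behavior_reference
#' @return The reference data frame with `t_recomputed`, `dof`, `p` columns
#'   appended.
#' @export
summary_comparisons <- function(demographics = FALSE) {
  ref <- behavior_reference(demographics = demographics)
  res <- lapply(seq_len(nrow(ref)), function(k) {
    ttest_from_summary(ref$mean_sdi[k], ref$sd_sdi[k], ref$n_sdi[k],
                       ref$mean_control[k], ref$sd_control[k],
                       ref$n_control[k])
  })
  ref$t_recomputed <- vapply(res, `[[`, 0, "t")
  ref$dof <- vapply(res, `[[`, 0, "dof")
  ref$p <- vapply(res, `[[`, 0, "p")
  ref
}

#' Regress a behavioral score on a network strength
#'
#' Simple one-predictor ordinary least squares of score on strength, with
#' the Pearson correlation, its two-sided p-value, and a Bonferroni
#' correction for the score-network comparison family.
#'
#' @param strengths Per-subject network strength (numeric vector).
#' @param scores Per-subject behavioral score (numeric vector, same length).
#' @param m_comparisons Bonferroni family size (default 8, the reference
#'   family of network-scale pairs).
#' @return List with `slope`, `intercept`, `r`, `p_raw`, `p_bonferroni`, `n`.
#' @export
regress_strength <- function(strengths, scores, m_comparisons = 8L) {
  if (length(strengths) != length(scores)) stopf("inputs must align")
  ok <- is.finite(strengths) & is.finite(scores)
  x <- strengths[ok]
  y <- scores[ok]
  if (length(x) < 3) stopf("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero-variance input")
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  p_raw <- ct$p.value
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate),
       p_raw = p_raw,
       p_bonferroni = min(1, m_comparisons * p_raw),
       n = length(x))
}

#' Regress every coupled network-scale pair in a behavior table
#'
#' @param behavior Data frame from [generate_behavior()] (or same layout).
#' @param strengths subjects x networks matrix aligned with `behavior`.
#' @param pairs Data frame with columns `network`, `scale`; defaults to the
#'   reference family: RECN and dDMN against impulsivity (BIS-11),
#'   behavioral approach (BAS), inhibition (BIS), and negative affect.
#' @param m_comparisons Bonferroni family size, default `nrow(pairs)`.
#' @return Data frame: one row per pair with slope, r, raw and corrected p.
#' @export
behavior_regressions <- function(behavior, strengths, pairs = NULL,
                                 m_comparisons = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(network = c("RECN", "dDMN"),
                         scale = c("BIS-11", "BAS", "BIS", "Negative Affect"),
                         stringsAsFactors = FALSE)
  }
  if (is.null(m_comparisons)) m_comparisons <- nrow(pairs)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    res <- regress_strength(strengths[, pairs$network[k]],
                            behavior[[pairs$scale[k]]],
                            m_comparisons = m_comparisons)
    data.frame(network = pairs$network[k], scale = pairs$scale[k],
               slope = res$slope, r = res$r, p_raw = res$p_raw,
               p_bonferroni = res$p_bonferroni, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chi-squared test of a 2 x 2 sex-by-group table
#'
#' Reports both the continuity-corrected and uncorrected chi-squared tests
#' of independence.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts.
#' @return List with `p_corrected`, `p_uncorrected`, and the two statistics.
#' @export
#' @examples
#' sex_ratio_test(matrix(c(22, 28, 25, 25), 2))
sex_ratio_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2) || any(counts < 0) ||
      any(counts != round(counts))) {
    stopf("counts must be a 2 x 2 table of nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("table has an empty margin")
  }
  if (all(counts[, 1] == counts[, 2])) {
    return(list(p_corrected = 1, p_uncorrected = 1,
                statistic_corrected = 0, statistic_uncorrected = 0))
  }
  corr <- stats::chisq.test(counts, correct = TRUE)
  unc <- stats::chisq.test(counts, correct = FALSE)
  list(p_corrected = corr$p.value, p_uncorrected = unc$p.value,
       statistic_corrected = unname(corr$statistic),
       statistic_uncorrected = unname(unc$statistic))
}
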