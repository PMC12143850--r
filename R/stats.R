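#' Bonferroni-adjusted per-test alpha
#'
#' Family-wise level divided by the number of tests, with the value rounded
#' half-up to three decimals alongside the exact threshold (a family of four
#' arousal measures at 0.05 gives 0.0125, reported as .013). Decisions always
#' use the exact value.
#'
#' @param family_alpha family-wise significance level
#' @param n_tests number of hypotheses in the family (>= 1)
#' @return list with \code{alpha} (exact) and \code{alpha_reported}
#'   (3-decimal half-up rounding)
#' @export
bonferroniAlpha <- function(family_alpha = 0.05, n_tests = 4) {
  if (!is.numeric(n_tests) || n_tests < 1) stopf("n_tests must be >= 1")
  a <- family_alpha / n_tests
  list(alpha = a, alpha_reported = roundHalfUp(a, 3))
}

#' Two-sided p-value from the t distribution
#'
#' \code{2 * (1 - F_t(|t|; df))}; the exact value is returned, with
#' \code{\link{roundP}} available for manuscript-style reporting.
#'
#' @param t t statistic
#' @param df degrees of freedom (>= 1)
#' @return two-sided probability
#' @export
tPValue <- function(t, df) {
  if (any(df < 1)) stopf("df must be >= 1")
  2 * pt(-abs(t), df)
}

#' Round a p-value for reporting
#'
#' Manuscript convention: three decimals below .01, two decimals at or above
#' .01 (so 0.00739 reports as .007 and 0.0657 as .07), rounding half up.
#'
#' @param p p-value(s)
#' @return rounded numeric value(s)
#' @export
roundP <- function(p) {
  ifelse(p < 0.01, roundHalfUp(p, 3), roundHalfUp(p, 2))
}

#' Paired t test on incident/reference pairs for one measure
#'
#' Computed from the defining formula on the differences
#' \code{d = incident - reference}: \code{t = mean(d) / (sd(d) / sqrt(n))},
#' two-sided p from the t distribution with \code{n - 1} degrees of freedom.
#' Group means and SDs of both sides are reported; the paired statistic
#' depends on the SD of the differences, which cannot be reconstructed from
#' the group SDs, so both are carried and neither is back-derived from the
#' other.
#'
#' @param incident,reference numeric vectors of equal length (one pair per
#'   usable incident)
#' @param measure label for the result row
#' @param alpha significance threshold applied to the two-sided p
#' @return one-row tibble of class \code{paired_comparison}: n_pairs, means,
#'   SDs, mean_diff, sd_diff, t, df, p (exact), p_reported, alpha,
#'   significant
#' @export
pairedT <- function(incident, reference, measure = "measure", alpha = 0.05) {
  ok <- is.finite(incident) & is.finite(reference)
  incident <- incident[ok]; reference <- reference[ok]
  n <- length(incident)
  if (n < 2L) stopf("paired t needs at least 2 complete pairs")
  d <- incident - reference
  sdd <- sd(d)
  if (sdd == 0) stopf("differences have zero variance: t statistic undefined")
  t_stat <- mean(d) / (sdd / sqrt(n))
  p <- tPValue(t_stat, n - 1)
  tibble::tibble(
    measure = measure, n_pairs = n,
    mean_incident = mean(incident), sd_incident = sd(incident),
    mean_reference = mean(reference), sd_reference = sd(reference),
    mean_diff = mean(d), sd_diff = sdd,
    t = t_stat, df = n - 1, p = p, p_reported = roundP(p),
    alpha = alpha, significant = p < alpha
  )
}

#' Paired-sample inference across the measure family
#'
#' Runs the paired t test for every measure table at the Bonferroni-adjusted
#' per-test level. A measure with fewer than two complete pairs (or
#' zero-variance differences) is reported as not testable rather than raising
#' an error, mirroring how sparse measures (e.g. HRV) drop out of inference.
#'
#' @param pairs named list; each element a data frame / tibble with columns
#'   \code{incident} and \code{reference}
#' @param family_alpha family-wise level (default 0.05)
#' @return tibble with one row per measure plus columns \code{alpha_adjusted}
#'   and \code{alpha_reported}; untestable measures have NA statistics
#' @export
runFamily <- function(pairs, family_alpha = 0.05) {
  adj <- bonferroniAlpha(family_alpha, length(pairs))
  rows <- lapply(names(pairs), function(m) {
    tab <- pairs[[m]]
    res <- tryCatch(
      pairedT(tab$incident, tab$reference, measure = m, alpha = adj$alpha),
      error = function(e) tibble::tibble(
        measure = m,
        n_pairs = sum(is.finite(tab$incident) & is.finite(tab$reference)),
        mean_incident = NA_real_, sd_incident = NA_real_,
        mean_reference = NA_real_, sd_reference = NA_real_,
        mean_diff = NA_real_, sd_diff = NA_real_,
        t = NA_real_, df = NA_real_, p = NA_real_, p_reported = NA_real_,
        alpha = adj$alpha, significant = NA
      )
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  out$alpha_adjusted <- adj$alpha
  out$alpha_reported <- adj$alpha_reported
  out
}
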