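#' Polygenic-score style association from summary statistics
#'
#' Tests the association of a genetically predicted exposure with the
#' outcome at a relaxed inclusion threshold: SNPs with exposure
#' `p < p_threshold` (default 1e-5) are LD-clumped at `r2 < r2_threshold`,
#' harmonized against the outcome, and combined with a fixed-effects IVW
#' model — the summary-statistic equivalent of regressing the outcome on a
#' polygenic risk score. Relaxing the threshold captures more trait
#' variance and increases power, at the cost of admitting pleiotropic SNPs
#' (more false positives); at the strict genome-wide threshold this reduces
#' exactly to the fixed-effects IVW of the strict instrument.
#'
#' @param exposure,outcome `gwas_sumstats` tibbles.
#' @param ld Pairwise LD source for [clump()] (matrix, long data frame, or
#'   `NULL` for independent SNPs).
#' @param p_threshold Inclusion threshold (strict `<`), default 1e-5.
#' @param r2_threshold Clumping threshold, default 0.001.
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @return A one-row `prs_result` tibble: `n_snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `p_threshold_used`, `r2_threshold_used`.
#' @examples
#' sim <- simulate_two_sample(sim_truth(beta_causal = 0.2, seed = 8))
#' prs_association(sim$exposure, sim$outcome)
#' @export
prs_association <- function(exposure, outcome, ld = NULL,
                            p_threshold = 1e-5, r2_threshold = 0.001,
                            palindrome_eaf_limit = 0.42) {
  score_snps <- select_instruments(exposure, p_threshold = p_threshold)
  if (nrow(score_snps) == 0) {
    abort(sprintf("no score SNPs: no exposure SNP has p < %g", p_threshold))
  }
  score_snps <- if (is.null(ld)) {
    suppressWarnings(clump(score_snps, ld = NULL,
                           r2_threshold = r2_threshold))
  } else {
    clump(score_snps, ld = ld, r2_threshold = r2_threshold)
  }
  hs <- harmonize(score_snps, outcome,
                  palindrome_eaf_limit = palindrome_eaf_limit)
  res <- mr_ivw(hs, model = "fixed")
  out <- dplyr::mutate(res, method = "prs_ivw_fe",
                       p_threshold_used = p_threshold,
                       r2_threshold_used = r2_threshold)
  class(out) <- unique(c("prs_result", class(out)))
  out
}

#' Analytic power of a two-sample MR test with a binary outcome
#'
#' Post-hoc power for detecting a causal log odds ratio `beta_target` per SD
#' of exposure, given the outcome GWAS size, its case fraction, and the
#' variance the instrument explains in the exposure. The IVW estimate
#' behaves asymptotically as a normal variable with standard error
#' `1 / sqrt(n r2 cf (1 - cf))`, so the two-sided power at level `alpha` is
#' `pnorm(lambda - z) + pnorm(-lambda - z)` with noncentrality
#' `lambda = sqrt(n r2 cf (1 - cf)) |beta_target|` and `z` the upper
#' `alpha/2` normal point. With `case_fraction = NULL` the continuous
#' outcome version (`lambda = sqrt(n r2) |beta|`) is used. Power is `alpha`
#' at `beta_target = 0` and non-decreasing in `n`, `r2` and `|beta|`.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Case fraction of the outcome GWAS, or `NULL` for a
#'   continuous outcome.
#' @param r2_instrument Variance explained in the exposure by the
#'   instrument (see [variance_explained()]).
#' @param beta_target Causal effect to detect (log OR per SD).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `n_outcome`, `case_fraction`,
#'   `r2_instrument`, `beta_target`, `alpha`, `power`.
#' @examples
#' mr_power(n_outcome = 11240, case_fraction = 5739 / 11240,
#'          r2_instrument = 0.02, beta_target = 0.3)
#' @export
mr_power <- function(n_outcome, case_fraction = NULL, r2_instrument,
                     beta_target, alpha = 0.05) {
  assert_scalar_number(r2_instrument, "r2_instrument", 0, 1)
  assert_scalar_number(alpha, "alpha", 0, 1, strict = TRUE)
  if (!is.null(case_fraction)) {
    assert_scalar_number(case_fraction, "case_fraction", 0, 1, strict = TRUE)
  }
  cf_term <- if (is.null(case_fraction)) {
    1
  } else {
    case_fraction * (1 - case_fraction)
  }
  lambda <- sqrt(n_outcome * r2_instrument * cf_term) * abs(beta_target)
  z <- qnorm(1 - alpha / 2)
  power <- pnorm(lambda - z) + pnorm(-lambda - z)
  tibble(n_outcome = n_outcome,
         case_fraction = case_fraction %||% NA_real_,
         r2_instrument = r2_instrument, beta_target = beta_target,
         alpha = alpha, power = power)
}

#' Bonferroni-corrected significance thresholds for a family of MR tests
#'
#' Splits the family-wise level over `m_tests` exposures: the strict
#' threshold is `alpha_family / m_tests`, and p-values between the strict
#' threshold and 0.05 fall in the suggestive band. Reported at full
#' precision (0.05/36 is about 1.39e-3, conventionally quoted rounded to
#' 1e-3).
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param m_tests Number of exposures tested.
#' @return A list with `strict` (scalar) and `suggestive_band`
#'   (length-2 vector `[strict, 0.05)`; empty when `strict >= 0.05`).
#' @examples
#' bonferroni_thresholds(m_tests = 36)
#' @export
bonferroni_thresholds <- function(alpha_family = 0.05, m_tests) {
  stopifnot(m_tests >= 1)
  strict <- alpha_family / m_tests
  band <- if (strict < 0.05) c(strict, 0.05) else numeric(0)
  list(strict = strict, suggestive_band = band)
}
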