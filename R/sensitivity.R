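#' Cochran's Q heterogeneity statistic
#'
#' Heterogeneity of the per-SNP Wald ratios around the fixed-effects IVW
#' estimate: `Q = sum(w_j (ratio_j - beta_ivw)^2)` with first-order weights
#' `w_j = gamma_j^2 / se_out_j^2`, chi-square with `J - 1` degrees of
#' freedom under homogeneity. Excess Q indicates per-SNP causal estimates
#' that disagree — a classic signature of horizontal pleiotropy.
#'
#' @param hs An [harmonize()] result with at least 2 kept pairs.
#' @return A one-row tibble: `q`, `df`, `pval`.
#' @export
cochran_q <- function(hs) {
  pairs <- estimation_pairs(hs, 2, "Cochran's Q")
  wr <- wald_ratios(pairs)
  beta_fe <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - beta_fe)^2)
  df <- nrow(wr) - 1L
  tibble(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Rucker's Q' heterogeneity statistic
#'
#' The weighted residual sum of squares around the MR-Egger fit, chi-square
#' with `J - 2` degrees of freedom: heterogeneity left over once the
#' intercept has absorbed any directional pleiotropy. By least squares
#' `Q' <= Q` always; the drop `Q - Q'` (1 df) is the model-choice statistic
#' for preferring Egger over IVW.
#'
#' @param hs An [harmonize()] result with at least 3 kept pairs.
#' @return A one-row tibble: `q_rucker`, `df`, `pval`, plus `q_diff` and
#'   `q_diff_pval` for the 1-df model-choice test.
#' @export
rucker_q <- function(hs) {
  pairs <- estimation_pairs(hs, 3, "Rucker's Q")
  fit <- mr_egger(pairs)
  qq <- cochran_q(pairs)
  qp <- fit$q_rucker
  df <- nrow(pairs) - 2L
  q_diff <- qq$q - qp
  tibble(q_rucker = qp, df = df,
         pval = pchisq(qp, df, lower.tail = FALSE),
         q_diff = q_diff,
         q_diff_pval = pchisq(q_diff, 1, lower.tail = FALSE))
}

#' Radial IVW regression and outlier detection
#'
#' The radial reparameterization regresses `ratio_j * sqrt(w_j)` on
#' `sqrt(w_j)` through the origin (weights `w_j = gamma_j^2/se_out_j^2`);
#' its slope is algebraically the fixed-effects IVW estimate, and each SNP's
#' squared residual `q_j = w_j (ratio_j - beta)^2` is its contribution to
#' Cochran's Q. SNPs whose `q_j` exceeds the upper-alpha chi-square(1) point
#' (Bonferroni-corrected, `alpha / J`, by default) are flagged as outliers.
#'
#' @param hs An [harmonize()] result with at least 2 kept pairs.
#' @param alpha_outlier Per-family outlier significance level.
#' @param bonferroni Divide `alpha_outlier` by the number of SNPs
#'   (default `TRUE`).
#' @return An `mr_radial` list: `result` (the slope as an `mr_result`,
#'   method `"ivw_radial"`), `outliers` (character vector of flagged SNP
#'   ids), and `coords` (per-SNP tibble with the radial plot coordinates
#'   `x = sqrt(w)`, `y = ratio * sqrt(w)`, contribution `q_j`, and
#'   `outlier` flag).
#' @export
radial_ivw <- function(hs, alpha_outlier = 0.05, bonferroni = TRUE) {
  pairs <- estimation_pairs(hs, 2, "radial IVW")
  wr <- wald_ratios(pairs)
  x <- sqrt(wr$weight)
  y <- wr$ratio * sqrt(wr$weight)
  beta <- sum(x * y) / sum(x^2)
  se_fixed <- 1 / sqrt(sum(x^2))
  q_j <- wr$weight * (wr$ratio - beta)^2
  thr <- qchisq(if (bonferroni) alpha_outlier / nrow(wr) else alpha_outlier,
                df = 1, lower.tail = FALSE)
  coords <- tibble(snp = wr$snp, x = x, y = y, ratio = wr$ratio,
                   q_j = q_j, outlier = q_j > thr)
  structure(
    list(result = mr_result("ivw_radial", nrow(wr), beta, se_fixed),
         outliers = wr$snp[coords$outlier],
         coords = coords,
         q_threshold = thr),
    class = "mr_radial"
  )
}

#' @export
print.mr_radial <- function(x, ...) {
  cat(sprintf("<mr_radial> slope %.4f (se %.4f), %d SNP(s), %d outlier(s)\n",
              x$result$beta, x$result$se, x$result$n_snp,
              length(x$outliers)))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-out IVW series
#'
#' Re-estimates the multiplicative random-effects IVW effect `J` times,
#' omitting one SNP at a time, in the input SNP order. A single influential
#' or pleiotropic SNP shows up as the omission that moves the estimate the
#' most.
#'
#' @param hs An [harmonize()] result with at least 2 kept pairs.
#' @return A tibble with one row per omitted SNP: `snp_omitted` plus the
#'   `mr_result` columns of the reduced fit.
#' @export
leave_one_out <- function(hs) {
  pairs <- estimation_pairs(hs, 2, "leave-one-out")
  purrr::map(seq_len(nrow(pairs)), function(j) {
    res <- mr_ivw(pairs[-j, ])
    dplyr::bind_cols(tibble(snp_omitted = pairs$snp[j]), as_tibble(res))
  }) |>
    purrr::list_rbind()
}

#' Steiger directionality test
#'
#' Orients the causal direction by comparing the variance the instrument
#' SNPs explain in the exposure versus the outcome (the pseudo-R-squared
#' `sum(z^2/(z^2+n))` on each side). A valid exposure-to-outcome instrument
#' should explain much more variance in the exposure. Significance of the
#' difference comes from Fisher's r-to-z transform of the two multiple
#' correlations with combined-sample standard error. For a binary outcome
#' the same pseudo-R-squared is used on the log-odds scale (no
#' liability-scale correction; flagged in the output).
#'
#' @param hs An [harmonize()] result.
#' @param exposure_meta,outcome_meta [trait_meta()] objects supplying sample
#'   sizes; default to the metadata attached by [harmonize()].
#' @return A one-row tibble: `r2_exposure`, `r2_outcome`, `direction`
#'   (`"exposure_to_outcome"` or `"outcome_to_exposure"`), `z_diff`,
#'   `pval`, and `outcome_scale_note`.
#' @export
mr_steiger <- function(hs, exposure_meta = NULL, outcome_meta = NULL) {
  exposure_meta <- exposure_meta %||% attr(hs, "exposure_meta", exact = TRUE)
  outcome_meta <- outcome_meta %||% attr(hs, "outcome_meta", exact = TRUE)
  if (is.null(exposure_meta) || is.null(outcome_meta)) {
    abort("mr_steiger() needs exposure and outcome trait metadata.")
  }
  pairs <- estimation_pairs(hs, 1, "Steiger test")
  n_exp <- exposure_meta$n_total
  n_out <- outcome_meta$n_total
  r2_exp <- sum((pairs$beta_exp / pairs$se_exp)^2 /
                  ((pairs$beta_exp / pairs$se_exp)^2 + n_exp))
  r2_out <- sum((pairs$beta_out / pairs$se_out)^2 /
                  ((pairs$beta_out / pairs$se_out)^2 + n_out))
  z_exp <- atanh(sqrt(r2_exp))
  z_out <- atanh(sqrt(r2_out))
  se_diff <- sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  z_diff <- (z_exp - z_out) / se_diff
  tibble(
    r2_exposure = r2_exp, r2_outcome = r2_out,
    direction = ifelse(r2_exp > r2_out, "exposure_to_outcome",
                       "outcome_to_exposure"),
    z_diff = z_diff, pval = p_from_z(z_diff),
    outcome_scale_note = if (outcome_meta$trait_type == "binary") {
      "pseudo-R2 on log-odds scale (no liability correction)"
    } else {
      "observed scale"
    }
  )
}

#' Classify agreement between a sensitivity estimator and IVW
#'
#' Concordance labelling for results tables: a sensitivity estimate whose
#' p-value does not reach `alpha` is `"uncertain"`; otherwise it `"agree"`s
#' with the IVW result when the effect direction matches and the magnitudes
#' are compatible, and `"disagree"`s otherwise. "Magnitude agrees" is
#' operationalized as overlapping 95% confidence intervals
#' (`method = "ci_overlap"`, default) or direction only
#' (`method = "sign_only"`).
#'
#' @param ivw The reference `mr_result` (typically [mr_ivw()]).
#' @param other The sensitivity `mr_result` (Egger, WME or MBE).
#' @param alpha Significance level for the `"uncertain"` gate.
#' @param method `"ci_overlap"` or `"sign_only"`.
#' @return One of `"agree"`, `"disagree"`, `"uncertain"`.
#' @export
classify_concordance <- function(ivw, other, alpha = 0.05,
                                 method = c("ci_overlap", "sign_only")) {
  method <- match.arg(method)
  if (is.na(other$pval) || other$pval >= alpha) return("uncertain")
  same_sign <- sign(other$beta) == sign(ivw$beta)
  magnitude_ok <- if (method == "ci_overlap") {
    other$ci_low <= ivw$ci_high && ivw$ci_low <= other$ci_high
  } else {
    TRUE
  }
  if (same_sign && magnitude_ok) "agree" else "disagree"
}

#' Full sensitivity battery for one exposure-outcome analysis
#'
#' Bundles the diagnostics run alongside a headline IVW estimate:
#' heterogeneity (Cochran Q and, with enough SNPs, Rucker Q' and the Egger
#' intercept test), radial outlier flags, the leave-one-out series, the
#' Steiger directionality verdict, and concordance labels for each
#' sensitivity estimator against IVW. Components whose SNP-count
#' preconditions fail are recorded as `NULL` rather than erroring.
#'
#' @param hs An [harmonize()] result.
#' @param alpha Significance level used for concordance labels and radial
#'   outliers.
#' @param n_boot,seed Bootstrap settings passed to the weighted-median and
#'   mode-based estimators.
#' @return A `sensitivity_report` list: `ivw`, `estimates` (stacked
#'   `mr_result` rows), `q`, `rucker`, `egger_intercept`, `radial`, `loo`,
#'   `steiger`, `concordance` (named character vector).
#' @export
sensitivity_report <- function(hs, alpha = 0.05, n_boot = 1000, seed = 1L) {
  pairs <- estimation_pairs(hs, 1, "sensitivity report")
  try_null <- function(f) tryCatch(f, error = function(e) NULL)

  ivw <- mr_ivw(pairs)
  estimates <- mr_all(pairs, n_boot = n_boot, seed = seed)
  egger <- estimates[estimates$method == "egger", ]
  concordance <- purrr::map_chr(
    setNames(c("egger", "wme", "mbe"), c("egger", "wme", "mbe")),
    function(mth) {
      row <- estimates[estimates$method == mth, ]
      if (nrow(row) == 0) "uncertain" else {
        classify_concordance(ivw, row, alpha = alpha)
      }
    })

  out <- list(
    ivw = ivw,
    estimates = estimates,
    q = try_null(cochran_q(pairs)),
    rucker = try_null(rucker_q(pairs)),
    egger_intercept = if (nrow(egger) > 0) {
      tibble(estimate = egger$intercept, se = egger$intercept_se,
             pval = egger$intercept_pval)
    } else NULL,
    radial = try_null(radial_ivw(pairs, alpha_outlier = alpha)),
    loo = try_null(leave_one_out(pairs)),
    steiger = try_null(mr_steiger(pairs,
                                  attr(hs, "exposure_meta", exact = TRUE),
                                  attr(hs, "outcome_meta", exact = TRUE))),
    concordance = concordance
  )
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  cat(sprintf("  IVW: beta %.4f (se %.4f), p %.3g, %d SNP(s)\n",
              x$ivw$beta, x$ivw$se, x$ivw$pval, x$ivw$n_snp))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran Q %.2f (df %d, p %.3g)\n", x$q$q, x$q$df,
                x$q$pval))
  }
  if (!is.null(x$rucker)) {
    cat(sprintf("  Rucker Q' %.2f (df %d, p %.3g)\n", x$rucker$q_rucker,
                x$rucker$df, x$rucker$pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4f (p %.3g)\n",
                x$egger_intercept$estimate, x$egger_intercept$pval))
  }
  if (!is.null(x$steiger)) {
    cat(sprintf("  Steiger: %s (p %.3g)\n", x$steiger$direction,
                x$steiger$pval))
  }
  cat("  concordance:",
      paste(names(x$concordance), x$concordance, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble(
    beta_ivw = x$ivw$beta, se_ivw = x$ivw$se, pval_ivw = x$ivw$pval,
    n_snp = x$ivw$n_snp,
    q = if (!is.null(x$q)) x$q$q else NA_real_,
    q_pval = if (!is.null(x$q)) x$q$pval else NA_real_,
    q_rucker = if (!is.null(x$rucker)) x$rucker$q_rucker else NA_real_,
    egger_intercept = if (!is.null(x$egger_intercept)) {
      x$egger_intercept$estimate
    } else NA_real_,
    egger_intercept_pval = if (!is.null(x$egger_intercept)) {
      x$egger_intercept$pval
    } else NA_real_,
    n_radial_outliers = if (!is.null(x$radial)) {
      length(x$radial$outliers)
    } else NA_integer_,
    steiger_direction = if (!is.null(x$steiger)) {
      x$steiger$direction
    } else NA_character_,
    egger_label = x$concordance[["egger"]],
    wme_label = x$concordance[["wme"]],
    mbe_label = x$concordance[["mbe"]]
  )
}
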