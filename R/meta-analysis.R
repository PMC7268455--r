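#' Fixed-effects inverse-variance meta-analysis of GWAS summary statistics
#'
#' Combines per-consortium association estimates SNP-by-SNP with
#' inverse-variance weights, the METAL-style fixed-effects model: for studies
#' i with aligned effects `beta_i` and standard errors `se_i`,
#' `w_i = 1/se_i^2`, `beta_meta = sum(w_i beta_i)/sum(w_i)`,
#' `se_meta = 1/sqrt(sum(w_i))`, with a two-sided normal p-value and the
#' across-study Cochran heterogeneity `q_het = sum(w_i (beta_i -
#' beta_meta)^2)`. Before combination, every study is aligned to the first
#' study's effect-allele frame using the same allele rules as
#' [harmonize()]; SNPs whose alleles cannot be reconciled (or that are
#' ambiguous palindromes) are excluded from that study with an audit entry.
#'
#' @param studies A list of `gwas_sumstats` tibbles (at least one). SNPs
#'   absent from some studies are combined over the studies that carry them.
#' @param palindrome_eaf_limit Frequency limit for resolving palindromic
#'   SNPs across studies; see [harmonize()].
#' @return A `gwas_sumstats` tibble on the first study's allele frame with
#'   the usual canonical columns (`n` = summed sample size) plus
#'   `n_studies` and `q_het`. Trait metadata is pooled when every study
#'   carries it.
#' @examples
#' sim <- simulate_two_sample(sim_truth(seed = 5))
#' splits <- split_consortia(sim$outcome, c(0.6, 0.4), seed = 2)
#' pooled <- meta_fixed(splits)
#' @export
meta_fixed <- function(studies, palindrome_eaf_limit = 0.42) {
  if (inherits(studies, "data.frame")) studies <- list(studies)
  stopifnot(length(studies) >= 1)
  ref <- as_tibble(studies[[1]])

  aligned <- purrr::imap(studies[-1], function(st, k) {
    st <- as_tibble(st)
    m <- match(st$snp, ref$snp)
    known <- !is.na(m)
    out <- st
    if (any(known)) {
      al <- align_alleles(ref$ea[m[known]], ref$oa[m[known]],
                          ref$eaf[m[known]],
                          st$ea[known], st$oa[known], st$eaf[known],
                          palindrome_eaf_limit = palindrome_eaf_limit)
      keep <- al$status %in% c("kept", "flipped")
      n_bad <- sum(!keep)
      if (n_bad > 0) {
        inform(sprintf(
          "meta_fixed: excluded %d SNP(s) from study %d (unresolvable alleles)",
          n_bad, k + 1))
      }
      flip <- al$status == "flipped"
      idx <- which(known)
      out$beta[idx[flip]] <- -out$beta[idx[flip]]
      out$eaf[idx[flip]] <- 1 - out$eaf[idx[flip]]
      out$ea[idx] <- ref$ea[m[known]]
      out$oa[idx] <- ref$oa[m[known]]
      if (any(!keep)) out <- out[-idx[!keep], , drop = FALSE]
    }
    out
  })
  studies_aligned <- c(list(ref), aligned)

  long <- purrr::list_rbind(purrr::imap(
    studies_aligned,
    function(st, k) dplyr::mutate(as_tibble(st), .study = k)))

  meta_tbl <- long |>
    dplyr::mutate(w = 1 / .data$se^2) |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(
      chr = dplyr::first(.data$chr),
      pos = dplyr::first(.data$pos),
      ea = dplyr::first(.data$ea),
      oa = dplyr::first(.data$oa),
      eaf_meta = weighted.mean(.data$eaf, .data$w),
      beta_meta = sum(.data$w * .data$beta) / sum(.data$w),
      se_meta = 1 / sqrt(sum(.data$w)),
      n_sum = sum(.data$n),
      n_studies = dplyr::n(),
      q_het = sum(.data$w * (.data$beta - .data$beta_meta)^2),
      .groups = "drop"
    ) |>
    dplyr::rename(eaf = "eaf_meta", beta = "beta_meta", se = "se_meta",
                  n = "n_sum") |>
    dplyr::mutate(p = p_from_z(.data$beta / .data$se)) |>
    dplyr::arrange(.data$chr, .data$pos, .data$snp)

  metas <- purrr::map(studies, gwas_trait)
  pooled_meta <- if (!any(purrr::map_lgl(metas, is.null))) {
    m1 <- metas[[1]]
    trait_meta(sub(" \\(study \\d+\\)$", "", m1$trait_name), m1$trait_type,
               n_total = sum(purrr::map_dbl(metas, "n_total")),
               n_cases = if (!is.null(m1$n_cases)) {
                 sum(purrr::map_dbl(metas, "n_cases"))
               } else NULL,
               unit_note = m1$unit_note)
  } else NULL

  out <- as_gwas_sumstats(
    meta_tbl[c(unname(SUMSTATS_COLS), "n_studies", "q_het")],
    meta = pooled_meta)
  out
}

#' Genomic inflation factor
#'
#' The median association chi-square divided by the median of the 1-df
#' chi-square distribution (about 0.4549). Values near 1 indicate a
#' well-calibrated GWAS; inflation suggests stratification or polygenicity.
#'
#' @param p Numeric vector of two-sided p-values, or a summary-statistics
#'   data frame (in which case z-scores are computed from `beta/se`).
#' @param z Alternatively, a numeric vector of association z-scores.
#' @return The scalar inflation factor.
#' @examples
#' lambda_gc(z = rnorm(1e4))
#' @export
lambda_gc <- function(p = NULL, z = NULL) {
  chi2 <- if (!is.null(z)) {
    z^2
  } else if (is.data.frame(p)) {
    (p$beta / p$se)^2
  } else if (!is.null(p)) {
    qchisq(p, df = 1, lower.tail = FALSE)
  } else {
    abort("supply `p` or `z`.")
  }
  median(chi2) / qchisq(0.5, df = 1)
}

#' Univariate LD score regression
#'
#' Regresses per-SNP association chi-square statistics on LD scores:
#' under a polygenic model `E[chi2_j] = intercept + N h2 l_j / M`, so the
#' slope estimates `h2 N / M` and the intercept captures confounding
#' inflation. The default weighting is iteratively reweighted least squares
#' with weights `1 / (2 mu_j^2)` (the approximate variance of a chi-square
#' with mean `mu_j`), refit twice from an ordinary least-squares start;
#' `weights = "ols"` gives the unweighted fit, exact on noiseless inputs.
#' Standard errors come from a delete-a-block jackknife over SNPs.
#'
#' @param df Data frame with columns `ld_score` and `chi2` (at least 50
#'   SNPs).
#' @param N GWAS sample size.
#' @param M Number of SNPs the heritability is spread over; defaults to
#'   `nrow(df)`.
#' @param weights `"irls"` (default) or `"ols"`.
#' @param n_blocks Number of jackknife blocks (default 200, reduced when
#'   there are fewer SNPs).
#' @return An `ldsc_fit` object with fields `intercept`, `h2`,
#'   `se_intercept`, `se_h2`, `M`, `N`, `mean_chi2`, `slope`, `n_snp`.
#'   Use [tidy()] / [glance()] for tibble views.
#' @examples
#' sim <- simulate_ldsc_inputs(M = 2000, h2 = 0.3, N = 20000, seed = 1)
#' ldsc_fit(sim, N = 20000)
#' @export
ldsc_fit <- function(df, N, M = nrow(df), weights = c("irls", "ols"),
                     n_blocks = 200) {
  weights <- match.arg(weights)
  if (nrow(df) < 50) abort("LD score regression needs at least 50 SNPs.")
  ell <- df$ld_score
  chi2 <- df$chi2
  if (stats::var(ell) < .Machine$double.eps) {
    abort("degenerate LD-score variance: cannot fit.")
  }

  fit_once <- function(ell, chi2) {
    co <- coef(lm(chi2 ~ ell))
    if (weights == "irls") {
      for (i in 1:2) {
        mu <- pmax(co[1] + co[2] * ell, 0.05)
        w <- 1 / (2 * mu^2)
        co <- coef(lm(chi2 ~ ell, weights = w))
      }
    }
    c(intercept = unname(co[1]), h2 = unname(co[2]) * M / N)
  }

  est <- fit_once(ell, chi2)
  n <- length(ell)
  B <- max(2L, min(n_blocks, floor(n / 2)))
  block_id <- ceiling(seq_len(n) / (n / B))
  jk <- vapply(seq_len(B), function(b) {
    keep <- block_id != b
    fit_once(ell[keep], chi2[keep])
  }, numeric(2))
  jk_mean <- rowMeans(jk)
  jk_se <- sqrt((B - 1) / B * rowSums((jk - jk_mean)^2))

  structure(
    list(intercept = est[["intercept"]], h2 = est[["h2"]],
         se_intercept = jk_se[[1]], se_h2 = jk_se[[2]],
         slope = est[["h2"]] * N / M, M = M, N = N,
         mean_chi2 = mean(chi2), n_snp = n, weights = weights,
         n_blocks = B),
    class = "ldsc_fit"
  )
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf(
    "<ldsc_fit> %d SNPs (M = %d, N = %s)\n  h2 = %.4f (SE %.4f)\n  intercept = %.4f (SE %.4f)\n  mean chi2 = %.4f\n",
    x$n_snp, x$M, format(x$N, big.mark = ","), x$h2, x$se_h2,
    x$intercept, x$se_intercept, x$mean_chi2))
  invisible(x)
}

#' @rdname ldsc_fit
#' @param x An `ldsc_fit` object.
#' @param ... Unused.
#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble(term = c("intercept", "h2"),
         estimate = c(x$intercept, x$h2),
         std.error = c(x$se_intercept, x$se_h2))
}

#' @rdname ldsc_fit
#' @export
glance.ldsc_fit <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, intercept = x$intercept,
         se_intercept = x$se_intercept, mean_chi2 = x$mean_chi2,
         n_snp = x$n_snp, M = x$M, N = x$N)
}
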