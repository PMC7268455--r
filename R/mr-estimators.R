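# All estimators consume the kept/flipped rows of an mr_harmonized tibble:
# per SNP j, gamma_j = beta_exp (instrument-exposure effect) and
# Gamma_j = beta_out (instrument-outcome effect, log-odds scale).

Z_CRIT <- function(alpha = 0.05) qnorm(1 - alpha / 2)

mr_result <- function(method, n_snp, beta, se, pval = p_from_z(beta / se),
                      ci_low = beta - Z_CRIT() * se,
                      ci_high = beta + Z_CRIT() * se, ...) {
  # force `...` in the caller's frame: tibble()'s sequential data mask must
  # not capture expressions like `se[1]` against the columns built here
  extras <- list(...)
  out <- tibble(method = method, n_snp = as.integer(n_snp), beta = beta,
                se = se, ci_low = ci_low, ci_high = ci_high, pval = pval)
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  class(out) <- unique(c("mr_result", class(out)))
  out
}

#' @export
tidy.mr_result <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.mr_result <- function(x, ...) {
  as_tibble(unclass(x))[c("method", "n_snp", "beta", "se", "pval")]
}

# Extract the estimation pairs from a harmonized set, with validation.
estimation_pairs <- function(hs, min_snps = 1, what = "estimation") {
  stopifnot(is.data.frame(hs))
  pairs <- if ("status" %in% names(hs)) kept_pairs(hs) else hs
  if (nrow(pairs) < min_snps) {
    abort(sprintf("insufficient SNPs: %s needs at least %d harmonized pair(s), got %d",
                  what, min_snps, nrow(pairs)))
  }
  if (any(pairs$se_exp <= 0) || any(pairs$se_out <= 0)) {
    abort("standard errors must be positive.")
  }
  pairs
}

#' Per-SNP Wald ratios
#'
#' The ratio estimate underlying every summary-data MR method: for SNP j,
#' `ratio_j = Gamma_j / gamma_j` with first-order delta-method standard
#' error `se_out_j / |gamma_j|`. The inverse of the first-order ratio
#' variance, `gamma_j^2 / se_out_j^2`, is the weight used by the IVW,
#' weighted-median and mode-based estimators; a second-order variance adding
#' the exposure-side term is available.
#'
#' @param hs An [harmonize()] result (kept/flipped rows are used).
#' @param weighting `"first_order"` (default) or `"second_order"` ratio
#'   variance.
#' @return A tibble with one row per SNP: `snp`, `ratio`, `se_ratio`,
#'   `weight` (unnormalized inverse-variance weight).
#' @export
wald_ratios <- function(hs, weighting = c("first_order", "second_order")) {
  weighting <- match.arg(weighting)
  pairs <- estimation_pairs(hs, 1, "wald_ratios")
  if (any(pairs$beta_exp == 0)) {
    abort("Wald ratios require nonzero instrument-exposure effects.")
  }
  ratio <- pairs$beta_out / pairs$beta_exp
  var1 <- pairs$se_out^2 / pairs$beta_exp^2
  v <- if (weighting == "first_order") {
    var1
  } else {
    var1 + pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4
  }
  tibble(snp = pairs$snp, ratio = ratio, se_ratio = sqrt(v), weight = 1 / v)
}

#' Single-SNP Wald ratio estimate
#'
#' @param hs A harmonized set with exactly one kept pair.
#' @return An `mr_result` tibble (method `"wald"`).
#' @export
mr_wald_ratio <- function(hs) {
  pairs <- estimation_pairs(hs, 1, "mr_wald_ratio")
  if (nrow(pairs) != 1) {
    abort("mr_wald_ratio() is defined for a single SNP; use mr_ivw() for more.")
  }
  wr <- wald_ratios(pairs)
  mr_result("wald", 1L, wr$ratio, wr$se_ratio)
}

#' Inverse-variance weighted causal estimate
#'
#' Combines the per-SNP Wald ratios by inverse-variance weighting,
#' algebraically a weighted least-squares regression of `Gamma_j` on
#' `gamma_j` through the origin with weights `1/se_out_j^2`:
#' `beta = sum(w gamma Gamma) / sum(w gamma^2)` with fixed-effects standard
#' error `1/sqrt(sum(w gamma^2))`. The default multiplicative random-effects
#' model inflates the standard error by `sqrt(max(1, Q/(J-1)))`, where `Q`
#' is Cochran's heterogeneity statistic ([cochran_q()]); the inflation is
#' floored at 1 so random effects never report more precision than fixed
#' effects. A single-SNP set reduces exactly to the Wald ratio.
#'
#' @param hs An [harmonize()] result.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` tibble (method `"ivw_mre"` or `"ivw_fe"`) with the
#'   heterogeneity-inflation factor in `overdispersion`.
#' @examples
#' sim <- simulate_two_sample(sim_truth(beta_causal = 0.3, seed = 2))
#' hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
#' mr_ivw(hs)
#' @export
mr_ivw <- function(hs, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  pairs <- estimation_pairs(hs, 1, "mr_ivw")
  J <- nrow(pairs)
  w <- 1 / pairs$se_out^2
  g <- pairs$beta_exp
  G <- pairs$beta_out
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- 1 / sqrt(sum(w * g^2))
  phi <- if (J > 1) {
    q <- cochran_q(pairs)$q
    max(1, sqrt(q / (J - 1)))
  } else {
    1
  }
  se <- if (model == "multiplicative_random") se_fixed * phi else se_fixed
  mr_result(if (model == "multiplicative_random") "ivw_mre" else "ivw_fe",
            J, beta, se, overdispersion = phi)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' unconstrained intercept: `Gamma_j = a + b gamma_j`, weights
#' `1/se_out_j^2`, after orienting every pair so `gamma_j >= 0` (the
#' orientation the intercept's directional-pleiotropy interpretation
#' requires). The slope `b` is the pleiotropy-corrected causal estimate; the
#' intercept `a` estimates the average directional pleiotropic effect, and
#' its test is the standard check for directional pleiotropy. Standard
#' errors are inflated by `sqrt(max(1, Q'/(J-2)))` with `Q'` the weighted
#' residual sum of squares (Rucker's Q). Requires at least three SNPs and
#' non-degenerate spread in `gamma`; the method is underpowered with few
#' instruments.
#'
#' @param hs An [harmonize()] result with at least 3 kept pairs.
#' @return An `mr_result` tibble (method `"egger"`) with columns
#'   `intercept`, `intercept_se`, `intercept_pval` and the residual
#'   heterogeneity `q_rucker`.
#' @export
mr_egger <- function(hs) {
  pairs <- estimation_pairs(hs, 3, "MR-Egger")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  g <- pairs$beta_exp * flip
  G <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  J <- length(g)
  if (stats::weighted.mean((g - weighted.mean(g, w))^2, w) <
        .Machine$double.eps) {
    abort("collinear design: all instrument effects equal after orientation.")
  }

  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * G)
  est <- unname(drop(solve(XtWX, XtWy)))
  resid <- G - drop(X %*% est)
  q_rucker <- sum(w * resid^2)
  infl <- max(1, sqrt(q_rucker / (J - 2)))
  se_model <- unname(sqrt(diag(solve(XtWX))))
  se <- se_model * infl

  mr_result("egger", J, est[2], se[2],
            intercept = est[1], intercept_se = se[1],
            intercept_pval = p_from_z(est[1] / se[1]),
            q_rucker = q_rucker)
}

weighted_median_est <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  n <- length(b)
  if (s[1] >= 0.5) return(b[1])
  if (s[n] <= 0.5) return(b[n])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Parametric bootstrap over the sampling distributions of the per-SNP
# effects; statistic recomputes ratios and weights on each draw.
ratio_bootstrap <- function(pairs, n_boot, seed, statistic) {
  if (n_boot < 1) return(NA_real_)
  with_local_seed(seed, {
    J <- nrow(pairs)
    reps <- vapply(seq_len(n_boot), function(b) {
      g <- rnorm(J, pairs$beta_exp, pairs$se_exp)
      G <- rnorm(J, pairs$beta_out, pairs$se_out)
      statistic(G / g, g^2 / pairs$se_out^2)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, with weights proportional
#' to the inverse first-order ratio variance `gamma_j^2 / se_out_j^2`
#' normalized to sum to one. The estimate interpolates between the two
#' ordered ratios whose cumulative weights straddle 0.5, and is consistent
#' when at least half of the weight comes from valid instruments — robust
#' where IVW is not. The standard error comes from a seeded parametric
#' bootstrap (per-SNP effects resampled from their normal sampling
#' distributions, ratios and weights recomputed).
#'
#' @param hs An [harmonize()] result with at least 3 kept pairs.
#' @param weighting Ratio-variance order for the weights; see
#'   [wald_ratios()].
#' @param n_boot Bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and reports `NA` for `se`, `ci` and `pval`.
#' @param seed Seed for the bootstrap.
#' @return An `mr_result` tibble (method `"wme"`) with `n_boot` recorded.
#' @export
mr_weighted_median <- function(hs, weighting = c("first_order",
                                                 "second_order"),
                               n_boot = 1000, seed = 1L) {
  weighting <- match.arg(weighting)
  pairs <- estimation_pairs(hs, 3, "weighted median")
  wr <- wald_ratios(pairs, weighting = weighting)
  beta <- weighted_median_est(wr$ratio, wr$weight)
  se <- ratio_bootstrap(pairs, n_boot, seed, weighted_median_est)
  mr_result("wme", nrow(pairs), beta, se, n_boot = as.integer(n_boot))
}

mode_est_factory <- function(phi, grid_n) {
  function(b, w) {
    w <- w / sum(w)
    h <- phi * 0.9 * min(sd(b), mad(b)) * length(b)^(-1 / 5)
    if (!is.finite(h) || h <= 0) {
      agg <- tapply(w, b, sum)
      return(as.numeric(names(agg))[which.max(agg)])
    }
    grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
    dens <- vapply(grid, function(x) sum(w * dnorm(x, b, h)), numeric(1))
    grid[which.max(dens)]
  }
}

#' Mode-based causal estimate
#'
#' Estimates the causal effect as the mode of the weighted kernel density of
#' the per-SNP Wald ratios (weights as in [mr_weighted_median()]): SNPs
#' cluster by the causal effect they imply, and the estimate follows the
#' largest cluster, so it is consistent when the modal cluster consists of
#' valid instruments even if most SNPs are invalid. The Gaussian kernel
#' bandwidth is `phi` times a robust modified-Silverman scale,
#' `0.9 min(sd, mad) J^(-1/5)`; the mode is located on a fixed fine grid
#' spanning the ratio range plus three bandwidths. Standard error by seeded
#' parametric bootstrap. This is the simple weighted form of the estimator.
#'
#' @param hs An [harmonize()] result with at least 3 kept pairs.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed Bootstrap settings as in [mr_weighted_median()].
#' @param grid_n Number of grid points for the mode search.
#' @return An `mr_result` tibble (method `"mbe"`) with the `bandwidth` used.
#' @export
mr_mode <- function(hs, phi = 1, n_boot = 1000, seed = 1L, grid_n = 512) {
  pairs <- estimation_pairs(hs, 3, "mode-based estimator")
  wr <- wald_ratios(pairs)
  est_fun <- mode_est_factory(phi, grid_n)
  beta <- est_fun(wr$ratio, wr$weight)
  h <- phi * 0.9 * min(sd(wr$ratio), mad(wr$ratio)) *
    nrow(pairs)^(-1 / 5)
  se <- ratio_bootstrap(pairs, n_boot, seed, est_fun)
  mr_result("mbe", nrow(pairs), beta, se,
            bandwidth = h, n_boot = as.integer(n_boot))
}

#' Convert a causal estimate to the odds-ratio scale
#'
#' Continuous exposures are reported as the odds ratio of the outcome per 1
#' SD increase in the exposure, `OR = exp(beta)`. Binary exposures are
#' reported per doubling of the odds of the exposure by raising the OR and
#' its confidence limits to the power `ln 2` (0.693): a unit change on the
#' exposure's log-odds scale is rescaled to a doubling of odds.
#'
#' @param res An `mr_result` tibble.
#' @param exposure_meta The exposure [trait_meta()] (`trait_type` selects
#'   the conversion); defaults to continuous when `NULL`.
#' @return `res` with columns `or`, `or_ci_low`, `or_ci_high` appended.
#' @examples
#' res <- mr_result("ivw_mre", 10L, beta = 0.5, se = 0.1)
#' to_odds_ratio(res, trait_meta("exposure", "continuous", 1e5))
#' @export
to_odds_ratio <- function(res, exposure_meta = NULL) {
  expo <- if (!is.null(exposure_meta) &&
                exposure_meta$trait_type == "binary") log(2) else 1
  dplyr::mutate(res,
                or = exp(.data$beta)^expo,
                or_ci_low = exp(.data$ci_low)^expo,
                or_ci_high = exp(.data$ci_high)^expo)
}

#' Run the full estimator battery on one harmonized set
#'
#' Convenience wrapper returning IVW (requested model), MR-Egger, weighted
#' median and mode-based estimates stacked in one tibble. Estimators whose
#' preconditions fail (e.g. too few SNPs for Egger) are skipped with a
#' message.
#'
#' @inheritParams mr_ivw
#' @inheritParams mr_weighted_median
#' @param phi Mode-based bandwidth multiplier.
#' @return An `mr_result` tibble with one row per method that could run.
#' @export
mr_all <- function(hs, model = "multiplicative_random", n_boot = 1000,
                   seed = 1L, phi = 1) {
  runners <- list(
    function() mr_ivw(hs, model = model),
    function() mr_egger(hs),
    function() mr_weighted_median(hs, n_boot = n_boot,
                                  seed = child_seed(seed, 1)),
    function() mr_mode(hs, phi = phi, n_boot = n_boot,
                       seed = child_seed(seed, 2))
  )
  rows <- purrr::map(runners, function(f) {
    tryCatch(f(), error = function(e) {
      inform(paste0("mr_all: skipped estimator (", conditionMessage(e), ")"))
      NULL
    })
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- unique(c("mr_result", class(out)))
  out
}
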