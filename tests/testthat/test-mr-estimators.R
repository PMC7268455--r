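test_that("the Wald ratio follows its arithmetic and symmetries", {
  hs <- make_hs(0.1, 0.01, 0.05, 0.02)
  res <- mr_wald_ratio(hs)
  expect_equal(res$beta, 0.5)
  expect_equal(res$se, 0.2)

  null <- mr_wald_ratio(make_hs(0.1, 0.01, 0, 0.02))
  expect_equal(null$beta, 0)

  neg <- mr_wald_ratio(make_hs(-0.1, 0.01, 0.05, 0.02))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.2)
})

test_that("single-SNP IVW degenerates to the Wald ratio under both models", {
  hs <- make_hs(0.08, 0.01, 0.02, 0.03)
  wald <- mr_wald_ratio(hs)
  for (model in c("fixed", "multiplicative_random")) {
    ivw <- mr_ivw(hs, model = model)
    expect_equal(ivw$beta, wald$beta, tolerance = 1e-14)
    expect_equal(ivw$se, wald$se, tolerance = 1e-14)
  }
  expect_equal(mr_ivw(hs)$overdispersion, 1)
})

test_that("IVW of identical ratios returns that ratio with no overdispersion", {
  g <- c(0.05, 0.1, 0.2)
  hs <- make_hs(g, rep(0.01, 3), 0.7 * g, rep(0.02, 3))
  res <- mr_ivw(hs)
  expect_equal(res$beta, 0.7, tolerance = 1e-12)
  expect_equal(res$overdispersion, 1)
  expect_equal(mr_ivw(hs, "fixed")$se, res$se)
})

test_that("IVW matches an independent weighted-least-squares-through-origin oracle", {
  for (seed in 1:10) {
    hs <- random_hs(J = 12, seed = seed)
    fit <- lm(beta_out ~ 0 + beta_exp, data = hs,
              weights = 1 / hs$se_out^2)       # independent WLS oracle
    res_fe <- mr_ivw(hs, model = "fixed")
    expect_equal(res_fe$beta, unname(coef(fit)), tolerance = 1e-10)
    # fixed-effects SE is the model-based (sigma = 1) WLS SE
    se_model <- sqrt(diag(vcov(fit)))[[1]] / summary(fit)$sigma
    expect_equal(res_fe$se, se_model, tolerance = 1e-10)
    # multiplicative random effects inflates by sqrt(max(1, Q/(J-1)))
    q <- cochran_q(hs)$q
    expect_equal(mr_ivw(hs)$se, se_model * sqrt(max(1, q / 11)),
                 tolerance = 1e-10)
  }
})

test_that("fixed-effects IVW is the precision-weighted average of Wald ratios", {
  for (seed in 11:15) {
    hs <- random_hs(J = 9, seed = seed)
    wr <- wald_ratios(hs)
    expect_equal(mr_ivw(hs, "fixed")$beta,
                 sum(wr$weight * wr$ratio) / sum(wr$weight),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers exact linear data with zero residual heterogeneity", {
  g <- c(0.02, 0.05, 0.09, 0.12, 0.2)
  hs <- make_hs(g, rep(0.01, 5), 0.01 + 0.4 * g, rep(0.02, 5))
  res <- mr_egger(hs)
  expect_equal(res$beta, 0.4, tolerance = 1e-10)
  expect_equal(res$intercept, 0.01, tolerance = 1e-10)
  expect_equal(res$q_rucker, 0, tolerance = 1e-16)
})

test_that("Egger refuses degenerate designs", {
  hs <- make_hs(rep(0.1, 5), rep(0.01, 5), rnorm(5), rep(0.02, 5))
  expect_error(mr_egger(hs), "collinear")
  expect_error(mr_egger(random_hs(J = 2)), "insufficient SNPs")
})

test_that("Egger matches an independent weighted-regression oracle", {
  for (seed in 1:10) {
    hs <- random_hs(J = 12, seed = seed)
    # oracle: lm with gamma-orientation applied by hand
    flip <- ifelse(hs$beta_exp < 0, -1, 1)
    g <- hs$beta_exp * flip
    G <- hs$beta_out * flip
    w <- 1 / hs$se_out^2
    fit <- lm(G ~ g, weights = w)
    res <- mr_egger(hs)
    expect_equal(res$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    sigma <- summary(fit)$sigma
    se_model <- sqrt(diag(vcov(fit))) / sigma
    infl <- max(1, sigma)
    expect_equal(res$se, unname(se_model[2]) * infl, tolerance = 1e-10)
    expect_equal(res$intercept_se, unname(se_model[1]) * infl,
                 tolerance = 1e-10)
    expect_equal(res$q_rucker, sum(w * residuals(fit)^2), tolerance = 1e-8)
  }
})

test_that("the weighted median reduces to the plain median at equal weights", {
  hs <- make_hs(rep(0.1, 3), rep(0.01, 3), 0.1 * c(1, 2, 3), rep(0.02, 3))
  res <- mr_weighted_median(hs, n_boot = 0)
  expect_equal(res$beta, 2)
  expect_true(is.na(res$se))
})

# Exhaustive cumulative-weight interpolation oracle.
wm_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  approx(cum, b, xout = 0.5, rule = 2)$y
}

test_that("the weighted median interpolates cumulative weights like the oracle", {
  # weights 1,1,2 on ratios 1,2,3
  hs <- make_hs(c(0.1, 0.1, sqrt(2) * 0.1), rep(0.01, 3),
                c(1, 2, 3) * c(0.1, 0.1, sqrt(2) * 0.1), rep(0.02, 3))
  wr <- wald_ratios(hs)
  expect_equal(wr$weight / min(wr$weight), c(1, 1, 2), tolerance = 1e-12)
  res <- mr_weighted_median(hs, n_boot = 0)
  expect_equal(res$beta, wm_oracle(wr$ratio, wr$weight), tolerance = 1e-12)

  for (seed in 1:8) {
    hs <- random_hs(J = 11, seed = seed)
    wr <- wald_ratios(hs)
    expect_equal(mr_weighted_median(hs, n_boot = 0)$beta,
                 wm_oracle(wr$ratio, wr$weight), tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap SEs are seeded and reproducible", {
  hs <- random_hs(J = 10, seed = 21)
  a <- mr_weighted_median(hs, n_boot = 200, seed = 7)
  b <- mr_weighted_median(hs, n_boot = 200, seed = 7)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("the mode-based estimator handles degenerate and clustered ratios", {
  g <- c(0.05, 0.1, 0.2)
  hs <- make_hs(g, rep(0.01, 3), 1.3 * g, rep(0.02, 3))
  expect_equal(mr_mode(hs, n_boot = 0)$beta, 1.3, tolerance = 1e-12)

  # a tight cluster at 0 against one outlier at 5: mode stays near 0
  hs2 <- make_hs(rep(0.1, 4), rep(0.01, 4),
                 c(0, 0, 0.001, 0.5), rep(0.02, 4))
  res <- mr_mode(hs2, n_boot = 0)
  expect_lt(abs(res$beta), res$bandwidth)
})

test_that("the mode estimate matches a direct grid-search KDE oracle", {
  for (seed in 1:5) {
    hs <- random_hs(J = 10, seed = seed)
    wr <- wald_ratios(hs)
    w <- wr$weight / sum(wr$weight)
    h <- 0.9 * min(sd(wr$ratio), mad(wr$ratio)) * 10^(-1 / 5)
    grid <- seq(min(wr$ratio) - 3 * h, max(wr$ratio) + 3 * h,
                length.out = 512)
    dens <- sapply(grid, function(x) sum(w * dnorm((x - wr$ratio) / h)) / h)
    expect_equal(mr_mode(hs, n_boot = 0)$beta, grid[which.max(dens)],
                 tolerance = 1e-12)
  }
})

test_that("the mode estimate stays inside the ratio range as bandwidth grows", {
  hs <- random_hs(J = 10, seed = 6)
  wr <- wald_ratios(hs)
  for (phi in c(0.5, 1, 2, 4)) {
    est <- mr_mode(hs, phi = phi, n_boot = 0)$beta
    expect_gte(est, min(wr$ratio) - 1e-9)
    expect_lte(est, max(wr$ratio) + 1e-9)
  }
})

test_that("all estimators share the expected sign equivariances", {
  hs <- random_hs(J = 10, seed = 41)
  est <- function(h) {
    c(ivw = mr_ivw(h)$beta,
      egger = mr_egger(h)$beta,
      wme = mr_weighted_median(h, n_boot = 0)$beta,
      mbe = mr_mode(h, n_boot = 0)$beta)
  }
  base <- est(hs)
  both <- dplyr::mutate(hs, beta_exp = -beta_exp, beta_out = -beta_out)
  expect_equal(est(both), base, tolerance = 1e-10)
  out_only <- dplyr::mutate(hs, beta_out = -beta_out)
  expect_equal(est(out_only), -base, tolerance = 1e-10)
})

test_that("odds-ratio conversion distinguishes trait types", {
  cont <- trait_meta("ldl", "continuous", 1e5)
  bin <- trait_meta("allergy", "binary", 1e5, n_cases = 2e4)

  null <- mr_result_for_test(beta = 0, se = 0.1)
  conv <- to_odds_ratio(null, cont)
  expect_equal(conv$or, 1)
  expect_lt(conv$or_ci_low, 1)
  expect_gt(conv$or_ci_high, 1)

  unit <- mr_result_for_test(beta = 1, se = 0.1)
  expect_equal(to_odds_ratio(unit, bin)$or, exp(1)^log(2))
  expect_equal(to_odds_ratio(unit, bin)$or, 2, tolerance = 1e-12)

  half <- mr_result_for_test(beta = 0.5, se = 0.1)
  conv <- to_odds_ratio(half, cont)
  expect_equal(conv$or, exp(0.5))
  z <- qnorm(0.975)
  expect_equal(conv$or_ci_low, exp(0.5 - z * 0.1), tolerance = 1e-12)
  expect_equal(conv$or_ci_high, exp(0.5 + z * 0.1), tolerance = 1e-12)
})

test_that("mr_all stacks the battery and skips infeasible estimators", {
  hs <- random_hs(J = 10, seed = 51)
  res <- mr_all(hs, n_boot = 50, seed = 1)
  expect_setequal(res$method, c("ivw_mre", "egger", "wme", "mbe"))
  small <- random_hs(J = 2, seed = 52)
  res2 <- suppressMessages(mr_all(small, n_boot = 0))
  expect_equal(res2$method, "ivw_mre")
})
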