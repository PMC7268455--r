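test_that("Cochran's Q is zero for homogeneous ratios and matches hand arithmetic", {
  g <- c(0.05, 0.1, 0.2)
  hs <- make_hs(g, rep(0.01, 3), 0.7 * g, rep(0.02, 3))
  res <- cochran_q(hs)
  expect_equal(res$q, 0, tolerance = 1e-18)
  expect_equal(res$pval, 1)

  # equal unit weights (gamma 1, se_out 1), ratios {0, 0, 3}:
  # beta_ivw = 1, Q = 1 + 1 + 4 = 6 on 2 df
  hs2 <- make_hs(rep(1, 3), rep(0.01, 3), c(0, 0, 3), rep(1, 3))
  res2 <- cochran_q(hs2)
  expect_equal(res2$q, 6, tolerance = 1e-12)
  expect_equal(res2$df, 2L)
  expect_equal(res2$pval, pchisq(6, 2, lower.tail = FALSE))
})

test_that("Q follows its null chi-square distribution", {
  withr::with_seed(61, {
    J <- 10
    qs <- replicate(500, {
      g <- rnorm(J, 0.1, 0.03)
      se_o <- rep(0.02, J)
      hs <- make_hs(g + rnorm(J, 0, 1e-6), rep(1e-6, J),
                    0.3 * g + rnorm(J, 0, se_o), se_o)
      cochran_q(hs)$q
    })
    expect_equal(mean(qs), J - 1, tolerance = 4 * sqrt(2 * (J - 1) / 500))
  })
})

test_that("Rucker's Q' vanishes on exact linear data while Q does not", {
  g <- c(0.02, 0.05, 0.09, 0.12, 0.2)
  hs <- make_hs(g, rep(0.01, 5), 0.05 + 0.4 * g, rep(0.02, 5))
  rq <- rucker_q(hs)
  expect_equal(rq$q_rucker, 0, tolerance = 1e-16)
  expect_gt(cochran_q(hs)$q, 1)
  expect_equal(rq$df, 3L)
})

test_that("Q' never exceeds Q and the 1-df gap behaves under the null", {
  for (seed in 1:10) {
    hs <- random_hs(J = 10, seed = seed)
    expect_lte(rucker_q(hs)$q_rucker, cochran_q(hs)$q + 1e-10)
  }
  withr::with_seed(62, {
    gaps <- replicate(300, {
      J <- 12
      g <- rnorm(J, 0.1, 0.03)
      se_o <- rep(0.02, J)
      hs <- make_hs(g + rnorm(J, 0, 1e-6), rep(1e-6, J),
                    0.3 * g + rnorm(J, 0, se_o), se_o)
      cochran_q(hs)$q - rucker_q(hs)$q_rucker
    })
    expect_equal(mean(gaps), 1, tolerance = 4 * sqrt(2 / 300))
  })
})

test_that("the radial slope is the fixed-effects IVW estimate and q_j decompose Q", {
  for (seed in 1:8) {
    hs <- random_hs(J = 10, seed = seed)
    rad <- radial_ivw(hs)
    expect_equal(rad$result$beta, mr_ivw(hs, "fixed")$beta,
                 tolerance = 1e-12)
    expect_equal(sum(rad$coords$q_j), cochran_q(hs)$q, tolerance = 1e-8)
  }
})

test_that("a planted outlier is the one SNP the radial test flags", {
  withr::with_seed(63, {
    J <- 21
    g <- rnorm(J, 0.1, 0.02)
    se_o <- rep(0.02, J)
    G <- 0.3 * g + rnorm(J, 0, se_o)
    G[7] <- (0.3 + 10 * se_o[7] / g[7]) * g[7]   # ratio displaced 10 SDs
    hs <- make_hs(g, rep(0.005, J), G, se_o)
    rad <- radial_ivw(hs)
    expect_equal(rad$outliers, hs$snp[7])
  })
})

test_that("leave-one-out is order-stable, conserving, and finds influential SNPs", {
  g <- rep(0.1, 4)
  hs <- make_hs(g, rep(0.01, 4), 0.5 * g, rep(0.02, 4))
  loo <- leave_one_out(hs)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$snp_omitted, hs$snp)
  full <- mr_ivw(hs)
  expect_true(all(abs(loo$beta - full$beta) < 1e-12))

  withr::with_seed(64, {
    J <- 15
    g <- rnorm(J, 0.1, 0.02)
    se_o <- rep(0.02, J)
    G <- 0.3 * g + rnorm(J, 0, se_o)
    G[3] <- G[3] + 12 * se_o[3]
    hs2 <- make_hs(g, rep(0.005, J), G, se_o)
    loo2 <- leave_one_out(hs2)
    full2 <- mr_ivw(hs2)
    expect_equal(which.max(abs(loo2$beta - full2$beta)), 3L)
  })
})

test_that("leave-one-out estimates bracket the full-sample estimate", {
  hs <- simulate_partial_pleiotropy_hs(J = 20, frac_invalid = 0,
                                       beta = 0, seed = 65)
  loo <- leave_one_out(hs)
  full <- mr_ivw(hs)
  expect_gte(full$beta, min(loo$beta))
  expect_lte(full$beta, max(loo$beta))
})

test_that("Steiger orients strong instruments exposure-to-outcome", {
  meta_e <- trait_meta("exposure", "continuous", 1e5)
  meta_o <- trait_meta("outcome", "binary", 1e5, n_cases = 5e4)
  # strong exposure side, weak outcome side
  hs <- make_hs(rep(0.1, 10), rep(0.005, 10), rep(0.002, 10),
                rep(0.005, 10))
  st <- mr_steiger(hs, meta_e, meta_o)
  expect_equal(st$direction, "exposure_to_outcome")
  expect_lt(st$pval, 1e-6)
  expect_gt(st$r2_exposure, st$r2_outcome)
})

test_that("equal variance explained gives a null Steiger verdict", {
  meta <- trait_meta("t", "continuous", 5e4)
  hs <- make_hs(rep(0.1, 5), rep(0.01, 5), rep(0.1, 5), rep(0.01, 5))
  st <- mr_steiger(hs, meta, meta)
  expect_equal(st$z_diff, 0)
  expect_equal(st$pval, 1)
})

test_that("swapping the dataset labels flips the Steiger verdict", {
  hs <- simulate_partial_pleiotropy_hs(J = 20, frac_invalid = 0,
                                       beta = 0.3, seed = 66)
  meta_e <- trait_meta("exposure", "continuous", 1e5)
  meta_o <- trait_meta("outcome", "binary", 11240, n_cases = 5739)
  fwd <- mr_steiger(hs, meta_e, meta_o)
  swapped <- dplyr::mutate(hs,
                           tmp_b = beta_exp, beta_exp = beta_out,
                           beta_out = tmp_b,
                           tmp_s = se_exp, se_exp = se_out,
                           se_out = tmp_s, tmp_b = NULL, tmp_s = NULL)
  class(swapped) <- class(hs)
  rev <- mr_steiger(swapped, meta_o, meta_e)
  expect_equal(fwd$direction, "exposure_to_outcome")
  expect_equal(rev$direction, "outcome_to_exposure")
  expect_equal(rev$z_diff, -fwd$z_diff, tolerance = 1e-12)
})

test_that("concordance labels follow the significance and agreement rules", {
  ivw <- mr_result_for_test(beta = 0.5, se = 0.1)
  expect_equal(classify_concordance(ivw, mr_result_for_test(0.4, 0.31)),
               "uncertain")          # p = 0.2 scale: not significant
  agree <- mr_result_for_test(0.45, 0.15)
  expect_lt(agree$pval, 0.05)
  expect_equal(classify_concordance(ivw, agree), "agree")
  opposite <- mr_result_for_test(-0.45, 0.15)
  expect_equal(classify_concordance(ivw, opposite), "disagree")
  # same sign but non-overlapping CIs: magnitude disagrees
  far <- mr_result_for_test(5, 0.5)
  expect_equal(classify_concordance(ivw, far), "disagree")
  expect_equal(classify_concordance(ivw, far, method = "sign_only"),
               "agree")
})

test_that("the sensitivity report assembles every diagnostic", {
  hs <- simulate_partial_pleiotropy_hs(J = 15, frac_invalid = 0,
                                       beta = 0.3, seed = 67)
  attr(hs, "exposure_meta") <- trait_meta("exposure", "continuous", 1e5)
  attr(hs, "outcome_meta") <- trait_meta("outcome", "binary", 11240,
                                         n_cases = 5739)
  rep <- suppressMessages(sensitivity_report(hs, n_boot = 50, seed = 3))
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(nrow(rep$loo), 15)
  expect_equal(sort(names(rep$concordance)), c("egger", "mbe", "wme"))
  expect_equal(rep$steiger$direction, "exposure_to_outcome")
  gl <- glance(rep)
  expect_equal(gl$n_snp, 15L)
  expect_true(is.finite(gl$q))
})
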