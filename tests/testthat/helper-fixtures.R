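# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A minimal valid summary-statistics tibble (not yet validated).
make_raw_sumstats <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    eaf <- runif(n, 0.1, 0.9)
    beta <- rnorm(n, 0, 0.05)
    se <- runif(n, 0.01, 0.03)
    tibble::tibble(
      snp = sprintf("rs%04d", seq_len(n)),
      chr = as.character(sample(1:22, n, replace = TRUE)),
      pos = sort(sample.int(1e6, n)),
      ea = sample(c("A", "T"), n, replace = TRUE),
      oa = sample(c("C", "G"), n, replace = TRUE),
      eaf = eaf, beta = beta, se = se,
      p = 2 * pnorm(-abs(beta / se)), n = 10000
    )
  })
}

# A harmonized set built directly from effect vectors (status all "kept").
make_hs <- function(gamma, se_gamma, Gamma, se_Gamma, eaf = NULL,
                    exposure_meta = NULL, outcome_meta = NULL) {
  J <- length(gamma)
  eaf <- eaf %||% rep(0.5, J)
  hs <- tibble::tibble(
    snp = sprintf("snp_%03d", seq_len(J)), chr = "1", pos = seq_len(J),
    ea = "A", oa = "G", eaf = eaf,
    beta_exp = gamma, se_exp = se_gamma, p_exp = 2 * pnorm(-abs(gamma / se_gamma)),
    eaf_out = eaf, beta_out = Gamma, se_out = se_Gamma,
    p_out = 2 * pnorm(-abs(Gamma / se_Gamma)),
    status = "kept"
  )
  attr(hs, "exposure_meta") <- exposure_meta
  attr(hs, "outcome_meta") <- outcome_meta
  class(hs) <- c("mr_harmonized", class(hs))
  hs
}

# Random harmonized set for oracle comparisons.
random_hs <- function(J = 12, seed = 1) {
  withr::with_seed(seed, {
    make_hs(gamma = rnorm(J, 0.1, 0.04),
            se_gamma = runif(J, 0.005, 0.02),
            Gamma = rnorm(J, 0.03, 0.05),
            se_Gamma = runif(J, 0.01, 0.05))
  })
}

# Simulate a scenario where a fraction of SNPs carry directional
# pleiotropy while the rest are valid; returns a harmonized set.
simulate_partial_pleiotropy_hs <- function(J = 50, frac_invalid = 0.4,
                                           beta = 0.3, gamma_mean = 0.1,
                                           gamma_sd = 0.03,
                                           pleio_mean = 0.06,
                                           pleio_sd = 0.03,
                                           n_exp = 1e5, n_out = 11240,
                                           cf = 5739 / 11240, seed = 1) {
  withr::with_seed(seed, {
    J_inv <- round(frac_invalid * J)
    gamma <- rnorm(J, gamma_mean, gamma_sd)
    alpha <- c(rep(0, J - J_inv), rnorm(J_inv, pleio_mean, pleio_sd))
    eaf <- runif(J, 0.1, 0.9)
    se_e <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se_o <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out * cf * (1 - cf))
    make_hs(gamma = gamma + rnorm(J, 0, se_e), se_gamma = se_e,
            Gamma = beta * gamma + alpha + rnorm(J, 0, se_o),
            se_Gamma = se_o, eaf = eaf)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-row mr_result via the internal constructor, for conversion tests.
mr_result_for_test <- function(beta, se, method = "ivw_mre", n_snp = 10L) {
  tidymr:::mr_result(method, n_snp, beta, se)
}
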