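#' Define the generating truth of a synthetic two-sample MR scenario
#'
#' A `sim_truth` object holds every parameter of the generative model behind
#' [simulate_two_sample()]: the true causal effect of the exposure on the
#' (binary) outcome, the distribution of true instrument effects, the
#' horizontal-pleiotropy model, the two GWAS sample sizes, and the seed. The
#' defaults emulate the setting the package is designed around: a
#' well-powered continuous-exposure GWAS (n = 100,000) instrumenting ~50
#' genome-wide-significant SNPs, against a rare-cancer case-control outcome
#' GWAS of 5739 cases and 5501 controls pooled across two consortia.
#'
#' Pleiotropy models for the direct SNP-outcome effect `alpha_j`:
#' \describe{
#'   \item{`none`}{`alpha_j = 0` (all instruments valid).}
#'   \item{`balanced`}{`alpha_j ~ N(0, pleio_sd)`: pleiotropy averages out,
#'     IVW stays consistent.}
#'   \item{`directional`}{`alpha_j ~ N(pleio_mean, pleio_sd)` with nonzero
#'     mean: biases IVW, detectable through the MR-Egger intercept.}
#'   \item{`inside_violating`}{`alpha_j` correlated with the instrument
#'     strength `gamma_j` (correlation `inside_rho`), violating the InSIDE
#'     assumption MR-Egger relies on.}
#' }
#'
#' @param beta_causal True causal effect, log-odds of outcome per unit of
#'   exposure.
#' @param n_snps Number of instrument SNPs to simulate.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleio_mean,pleio_sd Mean and SD of the direct effects `alpha_j`.
#'   `balanced` forces `pleio_mean = 0`; `none` forces both to 0.
#' @param gamma_mean,gamma_sd Mean and SD of true instrument effects on the
#'   exposure (SD units of exposure per allele).
#' @param n_exp,n_out Sample sizes of the exposure and outcome GWAS.
#' @param case_fraction Case fraction of the binary outcome GWAS.
#' @param inside_rho Correlation between `alpha_j` and `gamma_j` under
#'   `inside_violating`.
#' @param eaf_range Range from which effect-allele frequencies are drawn.
#' @param seed Integer seed; identical truth objects generate byte-identical
#'   datasets.
#' @return A `sim_truth` object (named list).
#' @examples
#' truth <- sim_truth(beta_causal = 0.3, n_snps = 50, seed = 42)
#' sim <- simulate_two_sample(truth)
#' sim$exposure
#' @export
sim_truth <- function(beta_causal = 0, n_snps = 50,
                      pleiotropy = c("none", "balanced", "directional",
                                     "inside_violating"),
                      pleio_mean = 0, pleio_sd = 0,
                      gamma_mean = 0.04, gamma_sd = 0.01,
                      n_exp = 1e5, n_out = 11240,
                      case_fraction = 5739 / 11240,
                      inside_rho = 0.5,
                      eaf_range = c(0.1, 0.9), seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snps < 1) abort("`n_snps` must be at least 1.")
  assert_scalar_number(case_fraction, "case_fraction", 0, 1, strict = TRUE)
  if (pleiotropy == "none") {
    pleio_mean <- 0
    pleio_sd <- 0
  }
  if (pleiotropy == "balanced" && pleio_mean != 0) {
    abort("balanced pleiotropy requires `pleio_mean = 0`.")
  }
  structure(
    list(beta_causal = beta_causal, n_snps = as.integer(n_snps),
         pleiotropy = pleiotropy, pleio_mean = pleio_mean,
         pleio_sd = pleio_sd, gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         n_exp = n_exp, n_out = n_out, case_fraction = case_fraction,
         inside_rho = inside_rho, eaf_range = eaf_range,
         seed = as.integer(seed)),
    class = "sim_truth"
  )
}

# Non-palindromic allele pairs used for simulated SNPs, so that
# harmonization never has to drop simulated instruments.
NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                               ncol = 2, byrow = TRUE)

# Standard errors of per-allele effect estimates under the usual
# large-sample approximation: var(beta_hat) ~ 1 / (2 p (1-p) n) for a
# standardized continuous trait, divided by cf(1-cf) on the log-odds scale
# of a case-control trait.
sumstat_se <- function(eaf, n, case_fraction = NULL) {
  v <- 1 / (2 * eaf * (1 - eaf) * n)
  if (!is.null(case_fraction)) {
    v <- v / (case_fraction * (1 - case_fraction))
  }
  sqrt(v)
}

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Generates matched exposure and outcome summary statistics for the SNPs of
#' a [sim_truth()] scenario. For SNP j the true exposure effect `gamma_j` is
#' drawn from the configured normal distribution, the direct (pleiotropic)
#' outcome effect `alpha_j` from the configured pleiotropy model, and the
#' true outcome effect is `Gamma_j = beta_causal * gamma_j + alpha_j`.
#' Observed effects add independent Gaussian noise in each sample, with
#' standard errors following the per-allele variance approximation
#' `se ~ 1/sqrt(2 eaf (1-eaf) n)` (scaled by `1/sqrt(cf (1-cf))` on the
#' log-odds scale of the binary outcome). The two noise streams are
#' independent, as the two-sample design assumes. The outcome is generated
#' directly on the summary (log-odds) scale; no individual-level sampling.
#'
#' @param truth A [sim_truth()] object.
#' @return A list with validated `gwas_sumstats` tibbles `exposure` and
#'   `outcome` (sharing SNP ids, positions, alleles and frequencies) and a
#'   `truth_table` tibble of per-SNP generating values (`gamma_true`,
#'   `alpha`, `Gamma_true`).
#' @examples
#' sim <- simulate_two_sample(sim_truth(beta_causal = 0.3, seed = 7))
#' with(sim$truth_table, coef(lm(Gamma_true ~ 0 + gamma_true)))
#' @export
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_local_seed(truth$seed, {
    J <- truth$n_snps
    snp <- sprintf("rs%07d", seq_len(J))
    chr <- as.character(sample(1:22, J, replace = TRUE))
    pos <- sort(sample.int(5e7, J))
    pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), J,
                                            replace = TRUE), , drop = FALSE]
    eaf <- runif(J, truth$eaf_range[1], truth$eaf_range[2])

    gamma_true <- rnorm(J, truth$gamma_mean, truth$gamma_sd)
    alpha <- switch(
      truth$pleiotropy,
      none = rep(0, J),
      balanced = rnorm(J, 0, truth$pleio_sd),
      directional = rnorm(J, truth$pleio_mean, truth$pleio_sd),
      inside_violating = {
        g_std <- if (truth$gamma_sd > 0) {
          (gamma_true - truth$gamma_mean) / truth$gamma_sd
        } else {
          rep(0, J)
        }
        truth$pleio_mean + truth$pleio_sd *
          (truth$inside_rho * g_std +
             sqrt(1 - truth$inside_rho^2) * rnorm(J))
      }
    )
    Gamma_true <- truth$beta_causal * gamma_true + alpha

    se_exp <- sumstat_se(eaf, truth$n_exp)
    se_out <- sumstat_se(eaf, truth$n_out, truth$case_fraction)
    beta_exp <- gamma_true + rnorm(J, 0, se_exp)
    beta_out <- Gamma_true + rnorm(J, 0, se_out)

    base <- tibble(snp = snp, chr = chr, pos = pos,
                   ea = pair[, 1], oa = pair[, 2], eaf = eaf)
    exposure <- dplyr::mutate(base, beta = beta_exp, se = se_exp,
                              p = p_from_z(beta_exp / se_exp),
                              n = truth$n_exp)
    outcome <- dplyr::mutate(base, beta = beta_out, se = se_out,
                             p = p_from_z(beta_out / se_out),
                             n = truth$n_out)
    list(
      exposure = as_gwas_sumstats(
        exposure,
        meta = trait_meta("simulated exposure", "continuous",
                          n_total = truth$n_exp)),
      outcome = as_gwas_sumstats(
        outcome,
        meta = trait_meta("simulated outcome", "binary",
                          n_total = truth$n_out,
                          n_cases = round(truth$case_fraction * truth$n_out))),
      truth_table = tibble(snp = snp, gamma_true = gamma_true, alpha = alpha,
                           Gamma_true = Gamma_true)
    )
  })
}

#' Split one GWAS into per-consortium sub-studies
#'
#' Decomposes a pooled summary-statistics table into sub-studies of the given
#' sample-size fractions, emulating GWAS data delivered separately by
#' consortia. Each sub-study's standard errors follow the per-study sample
#' size (`se / sqrt(fraction)` relative to pooled), and per-study estimates
#' are drawn conditionally on the pooled estimate: independent per-study
#' noise is recentred so the fixed-effects inverse-variance combination of
#' the splits reproduces the pooled estimate exactly. A single fraction of 1
#' therefore returns the pooled study unchanged.
#'
#' @param ds A `gwas_sumstats` tibble.
#' @param fractions Numeric vector of per-study sample-size fractions,
#'   summing to 1.
#' @param seed Integer seed for the per-study noise.
#' @return A list of `gwas_sumstats` tibbles, one per fraction.
#' @examples
#' sim <- simulate_two_sample(sim_truth(seed = 3))
#' splits <- split_consortia(sim$outcome, c(0.7, 0.3), seed = 9)
#' @export
split_consortia <- function(ds, fractions, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (any(fractions <= 0)) abort("`fractions` must be positive.")
  meta <- gwas_trait(ds)
  with_local_seed(seed, {
    K <- length(fractions)
    J <- nrow(ds)
    se_k <- lapply(fractions, function(f) ds$se / sqrt(f))
    noise <- lapply(se_k, function(s) rnorm(J, 0, s))
    w <- lapply(se_k, function(s) 1 / s^2)
    w_sum <- Reduce(`+`, w)
    noise_meta <- Reduce(`+`, Map(`*`, w, noise)) / w_sum
    purrr::map(seq_len(K), function(k) {
      beta_k <- ds$beta + noise[[k]] - noise_meta
      sub <- dplyr::mutate(as_tibble(ds),
                           beta = beta_k, se = se_k[[k]],
                           p = p_from_z(beta_k / se_k[[k]]),
                           n = .data$n * fractions[k])
      sub_meta <- if (!is.null(meta)) {
        trait_meta(paste0(meta$trait_name, " (study ", k, ")"),
                   meta$trait_type,
                   n_total = meta$n_total * fractions[k],
                   n_cases = if (!is.null(meta$n_cases)) {
                     meta$n_cases * fractions[k]
                   } else NULL,
                   unit_note = meta$unit_note)
      } else NULL
      as_gwas_sumstats(sub, meta = sub_meta)
    })
  })
}

#' Simulate a small LD reference panel with block structure
#'
#' Generates a genotype dosage matrix (individuals x SNPs, values 0/1/2)
#' whose SNPs fall into independent LD blocks with a target within-block
#' squared correlation. Haplotypes within a block copy a per-individual
#' template allele with probability `r2^(1/4)`, which yields pairwise allele
#' correlation `sqrt(r2)` and hence LD r-squared near the target; across
#' blocks SNPs are independent. All SNPs within a block share the block's
#' allele frequency (the copying construction only preserves marginal
#' frequencies when they are equal within a block).
#'
#' @param n_ind Number of individuals.
#' @param blocks A data frame (or list coercible to one) with columns `size`
#'   and `r2`: SNPs per block and target within-block r-squared.
#' @param freqs Optional numeric vector of per-block allele frequencies;
#'   drawn uniformly from (0.1, 0.9) when missing.
#' @param snp_ids Optional SNP identifiers (length = total SNPs); defaults
#'   to `panel_1 ... panel_M`.
#' @param seed Integer seed.
#' @return An `ld_panel` object: list with `genotypes` (matrix), `freqs`,
#'   `blocks`.
#' @examples
#' panel <- simulate_ld_panel(500, data.frame(size = c(3, 2), r2 = c(0.9, 0.2)))
#' dim(panel$genotypes)
#' @export
simulate_ld_panel <- function(n_ind, blocks, freqs = NULL, snp_ids = NULL,
                              seed = 1L) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "r2") %in% names(blocks)))
  if (any(blocks$size < 1)) abort("block sizes must be >= 1.")
  if (any(blocks$r2 < 0 | blocks$r2 > 1)) abort("block r2 must be in [0,1].")
  M <- sum(blocks$size)
  with_local_seed(seed, {
    if (is.null(freqs)) freqs <- runif(nrow(blocks), 0.1, 0.9)
    stopifnot(length(freqs) == nrow(blocks))
    geno <- matrix(0L, n_ind, M)
    snp_freq <- numeric(M)
    col0 <- 0L
    for (b in seq_len(nrow(blocks))) {
      m <- blocks$size[b]
      p <- freqs[b]
      s <- blocks$r2[b]^(1 / 4)
      block_geno <- matrix(0L, n_ind, m)
      for (hap in 1:2) {
        template <- rbinom(n_ind, 1, p)
        copy <- matrix(rbinom(n_ind * m, 1, s), n_ind, m)
        fresh <- matrix(rbinom(n_ind * m, 1, p), n_ind, m)
        block_geno <- block_geno + copy * template + (1L - copy) * fresh
      }
      geno[, col0 + seq_len(m)] <- block_geno
      snp_freq[col0 + seq_len(m)] <- p
      col0 <- col0 + m
    }
    snp_ids <- snp_ids %||% sprintf("panel_%d", seq_len(M))
    stopifnot(length(snp_ids) == M)
    colnames(geno) <- snp_ids
    structure(list(genotypes = geno, freqs = setNames(snp_freq, snp_ids),
                   blocks = blocks),
              class = "ld_panel")
  })
}

#' Pairwise LD (r-squared) from a reference panel
#'
#' @param panel An [simulate_ld_panel()] object, or a genotype dosage matrix
#'   with SNP ids as column names.
#' @return A symmetric matrix of squared Pearson correlations between SNP
#'   dosages; monomorphic SNPs get 0 off-diagonal.
#' @export
ld_matrix <- function(panel) {
  geno <- if (inherits(panel, "ld_panel")) panel$genotypes else panel
  sds <- apply(geno, 2, sd)
  r <- suppressWarnings(stats::cor(geno))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  if (any(sds == 0)) {
    mono <- which(sds == 0)
    r2[mono, ] <- 0
    r2[, mono] <- 0
    diag(r2) <- 1
  }
  r2
}

#' Simulate per-SNP LD scores and association chi-square statistics
#'
#' Generates the `(ld_score, chi2)` table LD score regression consumes,
#' under the polygenic model `E[chi2_j] = intercept + N h2 l_j / M`. In
#' stochastic mode each statistic is a scaled 1-df chi-square draw matching
#' that mean; in noiseless mode the statistic is set to its expectation
#' exactly (useful for exact-recovery checks).
#'
#' @param M Number of SNPs (and total SNPs assumed to carry the
#'   heritability).
#' @param h2 True SNP heritability.
#' @param N GWAS sample size.
#' @param intercept True regression intercept (1 = no confounding).
#' @param ell_dist Either a numeric vector of LD scores of length `M` or a
#'   function of `M` returning one; default uniform on (1, 200).
#' @param noiseless If `TRUE`, set each chi-square to its expectation.
#' @param seed Integer seed.
#' @return A tibble with columns `ld_score` and `chi2`.
#' @export
simulate_ldsc_inputs <- function(M, h2, N, intercept = 1,
                                 ell_dist = function(m) runif(m, 1, 200),
                                 noiseless = FALSE, seed = 1L) {
  with_local_seed(seed, {
    ell <- if (is.function(ell_dist)) ell_dist(M) else ell_dist
    stopifnot(length(ell) == M)
    mu <- intercept + N * h2 * ell / M
    chi2 <- if (noiseless) mu else mu * rchisq(M, df = 1)
    tibble(ld_score = ell, chi2 = chi2)
  })
}
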