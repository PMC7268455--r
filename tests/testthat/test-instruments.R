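test_that("instrument selection applies a strict threshold in p order", {
  raw <- make_raw_sumstats(n = 3)
  raw$p <- c(1e-9, 5e-8, 1e-7)
  ds <- suppressWarnings(as_gwas_sumstats(raw))
  sel <- select_instruments(ds, p_threshold = 5e-8)
  expect_equal(nrow(sel), 1)           # boundary value excluded: strict <
  expect_equal(sel$snp, raw$snp[1])

  flat <- suppressWarnings(
    as_gwas_sumstats(dplyr::mutate(make_raw_sumstats(10), p = 0.5)))
  expect_equal(nrow(select_instruments(flat)), 0)
})

test_that("instrument selection equals a brute-force filter on random data", {
  ds <- as_gwas_sumstats(make_raw_sumstats(n = 200, seed = 31))
  thr <- 0.3
  sel <- select_instruments(ds, p_threshold = thr)
  brute <- tibble::as_tibble(ds)[ds$p < thr, ]
  brute <- brute[order(brute$p, brute$chr, brute$pos, brute$snp), ]
  expect_equal(tibble::as_tibble(sel), brute, ignore_attr = TRUE)
})

test_that("clumping keeps everything when all SNPs are independent", {
  ds <- as_gwas_sumstats(make_raw_sumstats(n = 8, seed = 32))
  r2 <- diag(8)
  dimnames(r2) <- list(ds$snp, ds$snp)
  kept <- clump(ds, ld = r2)
  expect_setequal(kept$snp, ds$snp)
})

test_that("perfectly correlated SNPs collapse to the most significant", {
  raw <- make_raw_sumstats(n = 2, seed = 33)
  raw$chr <- c("1", "1")
  raw$p <- c(1e-10, 1e-9)
  ds <- suppressWarnings(as_gwas_sumstats(raw))
  r2 <- matrix(1, 2, 2, dimnames = list(ds$snp, ds$snp))
  kept <- clump(ds, ld = r2)
  expect_equal(kept$snp, raw$snp[which.min(raw$p)])
})

# Exhaustive greedy oracle, written independently of clump():
greedy_oracle <- function(df, r2m, thr) {
  df <- df[order(df$p, df$chr, df$pos, df$snp), ]
  kept <- character()
  remaining <- df$snp
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    drop <- vapply(remaining, function(s) {
      if (s == lead) return(TRUE)
      same_chr <- df$chr[df$snp == s] == df$chr[df$snp == lead]
      same_chr && r2m[lead, s] >= thr
    }, logical(1))
    remaining <- remaining[!drop]
  }
  kept
}

test_that("clumping matches the exhaustive greedy oracle on random LD", {
  for (seed in 1:5) {
    raw <- make_raw_sumstats(n = 10, seed = seed)
    raw$chr <- as.character(sample(1:2, 10, replace = TRUE))
    ds <- suppressMessages(as_gwas_sumstats(raw))
    r2m <- withr::with_seed(seed + 100, {
      m <- matrix(runif(100), 10, 10)
      m <- (m + t(m)) / 2
      diag(m) <- 1
      dimnames(m) <- list(ds$snp, ds$snp)
      m
    })
    thr <- 0.3
    kept <- clump(ds, ld = r2m, r2_threshold = thr)
    expect_setequal(kept$snp, greedy_oracle(tibble::as_tibble(ds), r2m, thr))
    # kept set is independent; first kept SNP is the global minimum p
    pairs <- t(combn(kept$snp, 2))
    same_chr <- ds$chr[match(pairs[, 1], ds$snp)] ==
      ds$chr[match(pairs[, 2], ds$snp)]
    expect_true(all(r2m[pairs[same_chr, , drop = FALSE]] < thr))
    expect_equal(kept$snp[1], ds$snp[which.min(ds$p)])
  }
})

test_that("missing LD entries are treated as independent with a warning", {
  raw <- make_raw_sumstats(n = 3, seed = 34)
  raw$chr <- "1"
  ds <- as_gwas_sumstats(raw)
  r2 <- matrix(1, 2, 2, dimnames = list(ds$snp[1:2], ds$snp[1:2]))
  expect_warning(kept <- clump(ds, ld = r2), "absent from the LD source")
  expect_true(ds$snp[3] %in% kept$snp)
})

test_that("harmonization keeps identical codings unchanged", {
  sim <- simulate_two_sample(sim_truth(n_snps = 12, seed = 35))
  hs <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(hs$status == "kept"))
  expect_equal(hs$beta_out, sim$outcome$beta)
  expect_equal(hs$eaf_out, sim$outcome$eaf)
})

test_that("swapped outcome alleles are flipped with negated effect", {
  sim <- simulate_two_sample(sim_truth(n_snps = 6, seed = 36))
  flipped_outcome <- dplyr::mutate(tibble::as_tibble(sim$outcome),
                                   ea2 = .data$oa, oa = .data$ea,
                                   ea = .data$ea2, ea2 = NULL,
                                   beta = -.data$beta, eaf = 1 - .data$eaf)
  hs <- harmonize(sim$exposure, flipped_outcome)
  expect_true(all(hs$status == "flipped"))
  expect_equal(hs$beta_out, sim$outcome$beta)   # flip restores orientation
  expect_equal(hs$eaf_out, sim$outcome$eaf)
})

test_that("palindromic SNPs are resolved by frequency or dropped", {
  base <- make_raw_sumstats(n = 1, seed = 37)
  pal <- function(eaf_exp, eaf_out, ea = "A", oa = "T", swap = FALSE) {
    e <- dplyr::mutate(base, ea = !!ea, oa = !!oa, eaf = eaf_exp)
    o <- dplyr::mutate(base, ea = if (swap) !!oa else !!ea,
                       oa = if (swap) !!ea else !!oa, eaf = eaf_out)
    harmonize(as_gwas_sumstats(e), as_gwas_sumstats(o))$status
  }
  expect_equal(pal(0.2, 0.25), "kept")             # same side, outside band
  expect_equal(pal(0.5, 0.2), "dropped_palindromic")  # ambiguous at 0.5
  expect_equal(pal(0.2, 0.5), "dropped_palindromic")
  expect_equal(pal(0.2, 0.45), "dropped_palindromic") # inside the 0.42 band
  expect_equal(pal(0.2, 0.8), "dropped_palindromic")  # opposite sides
  expect_equal(pal(0.2, 0.75, swap = TRUE), "flipped")  # resolvable swap
})

test_that("missing and mismatching SNPs are audited, counts conserved", {
  sim <- simulate_two_sample(sim_truth(n_snps = 10, seed = 38))
  outcome <- tibble::as_tibble(sim$outcome)
  outcome$ea[2:3] <- "A"; outcome$oa[2:3] <- "C"
  ins <- tibble::as_tibble(sim$exposure)
  ins$ea[2:3] <- "A"; ins$oa[2:3] <- "G"
  hs <- harmonize(as_gwas_sumstats(ins),
                  as_gwas_sumstats(outcome[-1, ]))
  expect_equal(sum(hs$status == "dropped_missing"), 1)
  expect_equal(sum(hs$status == "dropped_mismatch"), 2)
  expect_equal(nrow(hs), nrow(ins))    # conservation: one row per instrument
  expect_equal(nrow(kept_pairs(hs)), nrow(ins) - 3)
})

test_that("harmonization is idempotent", {
  sim <- simulate_two_sample(sim_truth(n_snps = 8, seed = 39))
  flipped_outcome <- dplyr::mutate(tibble::as_tibble(sim$outcome),
                                   ea2 = .data$oa, oa = .data$ea,
                                   ea = .data$ea2, ea2 = NULL,
                                   beta = -.data$beta, eaf = 1 - .data$eaf)
  hs1 <- harmonize(sim$exposure, flipped_outcome)
  # rebuild the outcome on the harmonized frame and harmonize again
  outcome2 <- tibble::tibble(
    snp = hs1$snp, chr = hs1$chr, pos = hs1$pos, ea = hs1$ea, oa = hs1$oa,
    eaf = hs1$eaf_out, beta = hs1$beta_out, se = hs1$se_out, p = hs1$p_out,
    n = 10000)
  hs2 <- harmonize(sim$exposure, as_gwas_sumstats(outcome2))
  expect_true(all(hs2$status == "kept"))
  expect_equal(hs2$beta_out, hs1$beta_out)
  expect_equal(hs2$eaf_out, hs1$eaf_out)
})

test_that("variance explained follows its fixed points and recovers truth", {
  expect_equal(variance_explained(tibble::tibble(beta = 0, se = 1, n = 100)),
               0)
  n <- 5000
  z <- sqrt(n)
  expect_equal(variance_explained(tibble::tibble(beta = z, se = 1, n = n)),
               0.5)
  # simulation recovery: z^2/(z^2+n) estimates each SNP's share of variance
  withr::with_seed(40, {
    n_ind <- 50000
    J <- 10
    reps <- 40
    r2_true <- 0.001 * (1:J)          # per-SNP variance shares
    est <- replicate(reps, {
      bet <- sqrt(r2_true / (2 * 0.25)) + rnorm(J, 0, 1 / sqrt(2 * 0.25 * n_ind))
      se <- rep(1 / sqrt(2 * 0.25 * n_ind), J)
      variance_explained(tibble::tibble(beta = bet, se = se, n = n_ind))
    })
    expect_lt(abs(mean(est) - sum(r2_true)), 3 * sd(est) / sqrt(reps))
  })
})
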