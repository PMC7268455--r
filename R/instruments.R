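COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Align candidate allele codings (ea/oa/eaf) onto a reference frame.
# Returns a tibble with a status per SNP: kept (same orientation), flipped
# (candidate effect allele is the reference other allele; caller must negate
# beta and reflect eaf), dropped_palindromic (A/T or C/G SNP whose strand
# cannot be resolved by frequency), dropped_mismatch (irreconcilable
# alleles). Palindromic SNPs are kept only when both frequencies for the
# aligned allele fall on the same side of 0.5 and outside
# (limit, 1 - limit).
align_alleles <- function(ref_ea, ref_oa, ref_eaf, ea, oa, eaf,
                          palindrome_eaf_limit = 0.42) {
  n <- length(ea)
  status <- rep("dropped_mismatch", n)

  same <- ea == ref_ea & oa == ref_oa
  swapped <- ea == ref_oa & oa == ref_ea
  cea <- unname(COMPLEMENT[ea])
  coa <- unname(COMPLEMENT[oa])
  strand_same <- !same & !swapped & cea == ref_ea & coa == ref_oa
  strand_swapped <- !same & !swapped & cea == ref_oa & coa == ref_ea

  status[same | strand_same] <- "kept"
  status[swapped | strand_swapped] <- "flipped"

  pal <- is_palindromic(ref_ea, ref_oa)
  if (any(pal)) {
    aligned_eaf <- ifelse(status == "flipped", 1 - eaf, eaf)
    lim <- palindrome_eaf_limit
    resolvable <- pal & status %in% c("kept", "flipped") &
      (ref_eaf - 0.5) * (aligned_eaf - 0.5) > 0 &
      pmin(ref_eaf, 1 - ref_eaf) < lim &
      pmin(aligned_eaf, 1 - aligned_eaf) < lim
    status[pal & status %in% c("kept", "flipped") & !resolvable] <-
      "dropped_palindromic"
  }
  tibble(status = status)
}

#' Select genome-wide significant instrument SNPs
#'
#' Keeps SNPs robustly associated with the exposure at the conventional
#' genome-wide threshold (strict `p < 5e-8` by default), ordered by
#' ascending p-value, ready for LD clumping.
#'
#' @param exposure A `gwas_sumstats` tibble for the exposure trait.
#' @param p_threshold Significance threshold; SNPs are kept iff
#'   `p < p_threshold` (strict inequality).
#' @return A `gwas_sumstats` tibble of the selected rows (possibly empty),
#'   trait metadata preserved.
#' @examples
#' sim <- simulate_two_sample(sim_truth(seed = 11))
#' select_instruments(sim$exposure)
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  meta <- gwas_trait(exposure)
  out <- as_tibble(exposure) |>
    dplyr::filter(.data$p < p_threshold) |>
    dplyr::arrange(.data$p, .data$chr, .data$pos, .data$snp)
  gwas_trait(out) <- meta
  class(out) <- unique(c("gwas_sumstats", class(out)))
  out
}

#' Greedy LD clumping
#'
#' Prunes candidate instruments to an approximately independent set:
#' repeatedly keep the remaining SNP with the lowest p-value (ties broken by
#' chromosome, position, then id) and discard every remaining SNP whose LD
#' with it is `r2 >= r2_threshold`. SNP pairs missing from the LD source are
#' treated as independent (`r2 = 0`) with a single logged warning;
#' cross-chromosome pairs are always independent.
#'
#' @param candidates A `gwas_sumstats` tibble (e.g. from
#'   [select_instruments()]).
#' @param ld Pairwise LD: a symmetric r-squared matrix with SNP ids as
#'   dimnames (see [ld_matrix()]), a data frame with columns
#'   `snp_a`, `snp_b`, `r2`, or `NULL` (all SNPs treated as independent,
#'   with a warning).
#' @param r2_threshold SNPs are discarded iff `r2 >= r2_threshold` with a
#'   kept SNP (so kept pairs satisfy the strict `r2 < r2_threshold`).
#' @return The kept subset, ordered by ascending p-value.
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001) {
  meta <- gwas_trait(candidates)
  df <- as_tibble(candidates) |>
    dplyr::arrange(.data$p, .data$chr, .data$pos, .data$snp)
  if (nrow(df) <= 1) {
    gwas_trait(df) <- meta
    class(df) <- unique(c("gwas_sumstats", class(df)))
    return(df)
  }

  missing_seen <- FALSE
  lookup <- if (is.null(ld)) {
    warn("no LD source supplied to clump(); treating all SNPs as independent")
    function(a, b) 0
  } else if (is.matrix(ld)) {
    function(a, b) {
      out <- rep(0, length(b))
      if (!a %in% rownames(ld)) {
        missing_seen <<- TRUE
        return(out)
      }
      ib <- match(b, colnames(ld))
      ok <- !is.na(ib)
      if (any(!ok)) missing_seen <<- TRUE
      out[ok] <- ld[a, ib[ok]]
      out
    }
  } else if (is.data.frame(ld)) {
    key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
    val <- c(ld$r2, ld$r2)
    function(a, b) {
      out <- val[match(paste(a, b), key)]
      if (anyNA(out)) missing_seen <<- TRUE
      out[is.na(out)] <- 0
      out
    }
  } else {
    abort("`ld` must be a matrix, a data frame, or NULL.")
  }

  keep <- logical(nrow(df))
  alive <- rep(TRUE, nrow(df))
  while (any(alive)) {
    i <- which(alive)[1]
    keep[i] <- TRUE
    alive[i] <- FALSE
    rest <- which(alive)
    if (length(rest) > 0) {
      r2 <- lookup(df$snp[i], df$snp[rest])
      r2[df$chr[rest] != df$chr[i]] <- 0
      alive[rest[r2 >= r2_threshold]] <- FALSE
    }
  }
  if (missing_seen) {
    warn("some SNP pairs were absent from the LD source; treated as r2 = 0")
  }
  out <- df[keep, ]
  gwas_trait(out) <- meta
  class(out) <- unique(c("gwas_sumstats", class(out)))
  out
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' Pairs each instrument SNP with its outcome association on a shared
#' effect-allele frame, the unit of all MR estimation. SNPs are matched by
#' id; identical allele coding is kept as-is; swapped coding (including
#' strand complements) flips the outcome effect (`beta_out` negated,
#' `eaf_out` reflected). Palindromic SNPs (A/T, C/G) are kept only when both
#' datasets' aligned effect-allele frequencies fall on the same side of 0.5
#' and outside `(palindrome_eaf_limit, 1 - palindrome_eaf_limit)`; otherwise
#' they are dropped as ambiguous. SNPs absent from the outcome or with
#' irreconcilable alleles are dropped with the reason recorded in `status`.
#'
#' @param instrument A `gwas_sumstats` tibble of instrument SNPs (exposure
#'   associations).
#' @param outcome A `gwas_sumstats` tibble for the outcome trait.
#' @param palindrome_eaf_limit Frequency limit for resolving palindromic
#'   SNPs (default 0.42).
#' @return An `mr_harmonized` tibble with one row per instrument SNP:
#'   `snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, exposure effect `beta_exp` /
#'   `se_exp` / `p_exp`, aligned outcome effect `beta_out` / `se_out` /
#'   `p_out` / `eaf_out`, and `status` (`kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_missing`, `dropped_mismatch`). Trait
#'   metadata rides along as attributes `exposure_meta` / `outcome_meta`;
#'   estimators use the kept/flipped rows (see [kept_pairs()]).
#' @examples
#' sim <- simulate_two_sample(sim_truth(beta_causal = 0.3, seed = 2))
#' hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
#' table(hs$status)
#' @export
harmonize <- function(instrument, outcome, palindrome_eaf_limit = 0.42) {
  ins <- as_tibble(instrument)
  out <- as_tibble(outcome)
  m <- match(ins$snp, out$snp)

  hs <- tibble(
    snp = ins$snp, chr = ins$chr, pos = ins$pos,
    ea = ins$ea, oa = ins$oa, eaf = ins$eaf,
    beta_exp = ins$beta, se_exp = ins$se, p_exp = ins$p,
    eaf_out = out$eaf[m], beta_out = out$beta[m], se_out = out$se[m],
    p_out = out$p[m],
    status = ifelse(is.na(m), "dropped_missing", NA_character_)
  )

  matched <- which(!is.na(m))
  if (length(matched) > 0) {
    mm <- m[matched]
    al <- align_alleles(ins$ea[matched], ins$oa[matched], ins$eaf[matched],
                        out$ea[mm], out$oa[mm], out$eaf[mm],
                        palindrome_eaf_limit = palindrome_eaf_limit)
    hs$status[matched] <- al$status
    flip <- matched[al$status == "flipped"]
    hs$beta_out[flip] <- -hs$beta_out[flip]
    hs$eaf_out[flip] <- 1 - hs$eaf_out[flip]
    bad <- matched[!al$status %in% c("kept", "flipped")]
    hs$beta_out[bad] <- NA_real_
    hs$se_out[bad] <- NA_real_
    hs$p_out[bad] <- NA_real_
    hs$eaf_out[bad] <- NA_real_
  }

  attr(hs, "exposure_meta") <- gwas_trait(instrument)
  attr(hs, "outcome_meta") <- gwas_trait(outcome)
  class(hs) <- unique(c("mr_harmonized", class(hs)))
  hs
}

#' Kept SNP pairs of a harmonized set
#'
#' @param hs An [harmonize()] result.
#' @return The rows with status `kept` or `flipped` (the pairs entering
#'   estimation), attributes preserved.
#' @export
kept_pairs <- function(hs) {
  keep <- hs$status %in% c("kept", "flipped")
  out <- hs[keep, ]
  attr(out, "exposure_meta") <- attr(hs, "exposure_meta", exact = TRUE)
  attr(out, "outcome_meta") <- attr(hs, "outcome_meta", exact = TRUE)
  class(out) <- unique(c("mr_harmonized", class(out)))
  out
}

#' Variance in a trait explained by an instrument
#'
#' Sums per-SNP variance contributions `r2_j = z_j^2 / (z_j^2 + n)` over the
#' instrument SNPs, assuming independence (which LD clumping provides).
#'
#' @param ds A data frame with `beta` and `se` columns (or `z`), e.g. a
#'   clumped instrument.
#' @param n Sample size; defaults to the per-row `n` column.
#' @return Instrument R-squared in `[0, 1]`.
#' @examples
#' sim <- simulate_two_sample(sim_truth(seed = 4))
#' variance_explained(select_instruments(sim$exposure))
#' @export
variance_explained <- function(ds, n = NULL) {
  z <- if ("z" %in% names(ds)) ds$z else ds$beta / ds$se
  n <- n %||% ds$n
  sum(z^2 / (z^2 + n))
}
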