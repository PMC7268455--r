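#' Describe the trait behind a set of GWAS summary statistics
#'
#' Trait metadata travels alongside a summary-statistics table and drives the
#' parts of the analysis that depend on what the trait is: binary traits are
#' measured on the log-odds scale and their causal estimates are rescaled to
#' an odds ratio per doubling of the exposure odds, while continuous traits
#' are interpreted per standard deviation; sample sizes feed the Steiger
#' directionality test and the power calculation.
#'
#' @param trait_name Character label for the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_total Total (effective) sample size of the GWAS.
#' @param n_cases Number of cases; required for binary traits.
#' @param unit_note Free-text unit annotation, e.g. `"per SD"` or
#'   `"log odds of liability"`.
#'
#' @return A `trait_meta` object (a named list with `trait_name`,
#'   `trait_type`, `n_total`, `n_cases`, `case_fraction`, `unit_note`).
#' @examples
#' trait_meta("telomere length", "continuous", n_total = 37684)
#' trait_meta("glioma", "binary", n_total = 11240, n_cases = 5739)
#' @export
trait_meta <- function(trait_name, trait_type = c("continuous", "binary"),
                       n_total, n_cases = NULL, unit_note = NULL) {
  trait_type <- match.arg(trait_type)
  assert_scalar_number(n_total, "n_total", lower = 1)
  if (trait_type == "binary") {
    if (is.null(n_cases)) {
      abort("binary traits must carry `n_cases`.")
    }
    assert_scalar_number(n_cases, "n_cases", lower = 1, upper = n_total)
  }
  case_fraction <- if (!is.null(n_cases)) n_cases / n_total else NULL
  unit_note <- unit_note %||%
    if (trait_type == "binary") "log odds" else "per SD"
  structure(
    list(trait_name = as.character(trait_name), trait_type = trait_type,
         n_total = n_total, n_cases = n_cases,
         case_fraction = case_fraction, unit_note = unit_note),
    class = "trait_meta"
  )
}

#' @export
print.trait_meta <- function(x, ...) {
  cat(sprintf("<trait_meta> %s (%s), n = %s%s\n", x$trait_name, x$trait_type,
              format(x$n_total, big.mark = ","),
              if (!is.null(x$n_cases)) {
                sprintf(" (%s cases, case fraction %.3f)",
                        format(x$n_cases, big.mark = ","), x$case_fraction)
              } else ""))
  invisible(x)
}

# Canonical on-disk column names, in canonical order.
SUMSTATS_COLS <- c(SNP = "snp", CHR = "chr", POS = "pos", EA = "ea",
                   OA = "oa", EAF = "eaf", BETA = "beta", SE = "se",
                   P = "p", N = "n")

#' Get or set the trait metadata attached to a summary-statistics table
#'
#' @param ds A summary-statistics tibble (see [as_gwas_sumstats()]).
#' @param value A [trait_meta()] object.
#' @return The `trait_meta` object (or `NULL` when none is attached).
#' @export
gwas_trait <- function(ds) attr(ds, "trait", exact = TRUE)

#' @rdname gwas_trait
#' @export
`gwas_trait<-` <- function(ds, value) {
  stopifnot(is.null(value) || inherits(value, "trait_meta"))
  attr(ds, "trait") <- value
  ds
}

#' Audit log of rows dropped during validation
#'
#' @param ds A validated summary-statistics tibble.
#' @return A tibble with one row per drop reason (`reason`, `n_dropped`).
#' @export
gwas_audit <- function(ds) {
  attr(ds, "audit", exact = TRUE) %||%
    tibble(reason = character(), n_dropped = integer())
}

#' Validate a data frame of GWAS summary statistics
#'
#' Checks the per-SNP invariants a downstream MR analysis relies on and drops
#' rows that violate them, recording the count per reason in an audit log
#' (retrievable via [gwas_audit()]). Alleles are upper-cased; duplicated SNP
#' identifiers keep their first occurrence; p-values of exactly zero are
#' floored to the smallest positive double (with a warning) so that
#' downstream log and quantile transforms stay finite. A row is dropped when
#' any of: a mandatory field is missing or non-finite, the two alleles are
#' not distinct single bases in A/C/G/T, `eaf` is outside (0,1), `se <= 0`,
#' `p` is outside (0,1], or `n <= 0`. Stored p-values inconsistent with the
#' two-sided normal p implied by `beta/se` trigger a warning only, since
#' published files are routinely rounded.
#'
#' @param df A data frame with columns `snp`, `chr`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `p`, `n` (see [read_gwas()] for mapping other
#'   dialects onto these names).
#' @param meta Optional [trait_meta()] to attach.
#' @param p_tolerance Tolerance, in log10 units, for the stored-vs-recomputed
#'   p-value consistency warning.
#' @return A validated tibble of class `gwas_sumstats` with the audit log and
#'   trait metadata as attributes.
#' @export
as_gwas_sumstats <- function(df, meta = NULL, p_tolerance = 0.5) {
  needed <- unname(SUMSTATS_COLS)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra_cols <- setdiff(names(df), needed)
  ds <- as_tibble(df)[c(needed, extra_cols)]
  ds$snp <- as.character(ds$snp)
  ds$chr <- as.character(ds$chr)
  ds$pos <- as.integer(ds$pos)
  ds$ea <- toupper(as.character(ds$ea))
  ds$oa <- toupper(as.character(ds$oa))
  for (col in c("eaf", "beta", "se", "p", "n")) {
    ds[[col]] <- as.numeric(ds[[col]])
  }

  audit <- list()
  drop <- function(keep, reason) {
    n_bad <- sum(!keep)
    if (n_bad > 0) audit[[reason]] <<- n_bad
    ds <<- ds[keep, ]
  }

  drop(complete.cases(ds[c("snp", "ea", "oa", "eaf", "beta", "se", "p", "n")]),
       "missing_field")
  bases <- c("A", "C", "G", "T")
  drop(ds$ea %in% bases & ds$oa %in% bases, "non_acgt_allele")
  drop(ds$ea != ds$oa, "identical_alleles")
  drop(ds$eaf > 0 & ds$eaf < 1, "eaf_out_of_range")
  drop(ds$se > 0, "nonpositive_se")
  drop(ds$n > 0, "nonpositive_n")
  n_zero_p <- sum(ds$p == 0)
  if (n_zero_p > 0) {
    warn(sprintf("%d p-value(s) of 0 floored to %.3g", n_zero_p,
                 .Machine$double.xmin))
    ds$p[ds$p == 0] <- .Machine$double.xmin
  }
  drop(ds$p > 0 & ds$p <= 1, "p_out_of_range")
  drop(!duplicated(ds$snp), "duplicate_snp_id")

  if (nrow(ds) > 0) {
    p_implied <- p_from_z(ds$beta / ds$se)
    # clamp to -300 on the log10 scale so underflowed p-values still
    # compare (both "effectively zero" counts as consistent)
    lp <- function(x) pmax(log10(pmax(x, 1e-320)), -300)
    off <- abs(lp(ds$p) - lp(p_implied)) > p_tolerance
    if (any(off)) {
      warn(sprintf(
        "%d row(s) have stored p-values inconsistent with beta/se (>%.1f log10 units); kept as-is",
        sum(off, na.rm = TRUE), p_tolerance))
    }
  }

  audit_tbl <- tibble(reason = names(audit),
                      n_dropped = as.integer(unlist(audit)))
  if (nrow(audit_tbl) > 0) {
    inform(paste0("dropped ", sum(audit_tbl$n_dropped), " row(s): ",
                  paste(sprintf("%s (%d)", audit_tbl$reason,
                                audit_tbl$n_dropped), collapse = ", ")))
  }
  attr(ds, "audit") <- audit_tbl
  gwas_trait(ds) <- meta
  class(ds) <- unique(c("gwas_sumstats", class(ds)))
  ds
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-rowed delimited file, maps its columns onto the canonical
#' per-SNP fields, and validates the result with [as_gwas_sumstats()]. The
#' canonical on-disk header is `SNP CHR POS EA OA EAF BETA SE P N`; files in
#' other dialects are handled by `column_map`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(SNP = "rsid", BETA = "effect")`. Canonical
#'   names not listed are looked up verbatim (case-insensitively).
#' @param meta Optional [trait_meta()] to attach.
#' @param delim Field delimiter; default tab.
#' @return A validated `gwas_sumstats` tibble.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' truth <- sim_truth(beta_causal = 0.2, n_snps = 20, seed = 1)
#' write_gwas(simulate_two_sample(truth)$exposure, path)
#' ds <- read_gwas(path)
#' @export
read_gwas <- function(path, column_map = NULL, meta = NULL, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) abort(sprintf("no data rows in '%s'", path))
  wanted <- setNames(names(SUMSTATS_COLS), names(SUMSTATS_COLS))
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  idx <- match(tolower(wanted), tolower(names(raw)))
  if (anyNA(idx)) {
    abort(paste0("missing mandatory column(s) in '", path, "': ",
                 paste(wanted[is.na(idx)], collapse = ", ")))
  }
  df <- raw[idx]
  names(df) <- unname(SUMSTATS_COLS)
  ds <- as_gwas_sumstats(df, meta = meta)
  if (nrow(ds) == 0) abort(sprintf("no valid rows in '%s'", path))
  ds
}

#' Write GWAS summary statistics to a canonical TSV
#'
#' Writes the canonical nine-field (plus sample size) tab-separated layout
#' with header `SNP CHR POS EA OA EAF BETA SE P N`, rows sorted by
#' `(chr, pos)` so output is deterministic regardless of input row order.
#'
#' @param ds A `gwas_sumstats` tibble (or any data frame with the canonical
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(ds, path) {
  out <- as_tibble(ds)[unname(SUMSTATS_COLS)]
  out <- dplyr::arrange(out, .data$chr, .data$pos, .data$snp)
  names(out) <- names(SUMSTATS_COLS)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Association z-scores
#'
#' The Wald z-statistic `beta / se` underlying the genomic inflation factor,
#' LD score regression, and the Steiger directionality test.
#'
#' @param x A summary-statistics data frame (a `z` column is appended) or a
#'   numeric vector of effect sizes.
#' @param ... Passed to methods.
#' @return For data frames, the input tibble with a `z` column; for numeric
#'   vectors, the vector `x / se`.
#' @examples
#' zscore(0.1, se = 0.05)
#' @export
zscore <- function(x, ...) UseMethod("zscore")

#' @rdname zscore
#' @param se Numeric vector of standard errors (numeric method only).
#' @export
zscore.numeric <- function(x, se, ...) {
  if (any(se <= 0)) abort("`se` must be positive.")
  x / se
}

#' @rdname zscore
#' @export
zscore.data.frame <- function(x, ...) {
  dplyr::mutate(as_tibble(x), z = .data$beta / .data$se)
}
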