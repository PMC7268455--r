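#' Configure a multi-exposure MR study
#'
#' Collects everything [run_study()] needs: the exposure GWAS (one per
#' candidate risk factor), the outcome GWAS (one or more consortium files,
#' meta-analysed when several), optional LD information for clumping, the
#' thresholds of the design, and the seed that makes the whole run
#' reproducible.
#'
#' @param exposures Named list of exposure datasets: each element a
#'   `gwas_sumstats` tibble (with [trait_meta()] attached) or a file path
#'   for [read_gwas()]. Names label the risk factors.
#' @param outcome_studies List of outcome datasets (tibbles or paths); more
#'   than one is combined with [meta_fixed()].
#' @param subtype Label for the outcome stratum (e.g. `"all glioma"`,
#'   `"GBM"`); subtype analyses are separate configs over different outcome
#'   files, not a special code path.
#' @param ld Optional LD source for [clump()].
#' @param p_instrument Instrument significance threshold (default 5e-8).
#' @param r2_clump LD clumping threshold (default 0.001).
#' @param alpha Family-wise significance level (default 0.05) split by
#'   Bonferroni over the exposures.
#' @param n_boot Bootstrap replicates for the sensitivity estimators.
#' @param seed Integer seed; mandatory.
#' @param sensitivity_all Run the sensitivity battery for every exposure,
#'   not only those reaching the suggestive tier.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposures, outcome_studies, subtype = "all",
                            ld = NULL, p_instrument = 5e-8,
                            r2_clump = 0.001, alpha = 0.05, n_boot = 1000,
                            seed = 1L, sensitivity_all = FALSE) {
  if (length(exposures) < 1) abort("need at least one exposure.")
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    abort("`exposures` must be a named list.")
  }
  if (inherits(outcome_studies, "data.frame") ||
        is.character(outcome_studies)) {
    outcome_studies <- list(outcome_studies)
  }
  if (length(outcome_studies) < 1) abort("need at least one outcome study.")
  if (is.null(seed)) abort("`seed` is mandatory for a reproducible run.")
  structure(
    list(exposures = exposures, outcome_studies = outcome_studies,
         subtype = subtype, ld = ld, p_instrument = p_instrument,
         r2_clump = r2_clump, alpha = alpha, n_boot = n_boot,
         seed = as.integer(seed), sensitivity_all = sensitivity_all),
    class = "analysis_config"
  )
}

resolve_dataset <- function(x) {
  if (is.character(x)) read_gwas(x) else x
}

#' Run the full MR study design across many exposures
#'
#' Executes the whole analysis plan of a systematic multi-risk-factor MR
#' study: meta-analyse the outcome consortium files; for each exposure,
#' select genome-wide significant instruments, LD-clump, harmonize against
#' the outcome and estimate the causal effect by multiplicative
#' random-effects IVW on the odds-ratio scale; assign Bonferroni tiers
#' (strict `alpha/m`, suggestive `[alpha/m, 0.05)`); run the sensitivity
#' battery (Egger, weighted median, mode-based, heterogeneity, Steiger) for
#' exposures reaching at least the suggestive tier; and compute post-hoc
#' power for each row. Exposures whose instrument construction fails are
#' reported as skipped rows rather than aborting the study. The run is
#' deterministic given the config: every stochastic step derives its seed
#' from `cfg$seed`.
#'
#' @param cfg An [analysis_config()].
#' @return A `results_rows` tibble, one row per exposure, sorted by
#'   ascending IVW p-value (skipped rows last): `risk_factor`, `subtype`,
#'   `n_snp`, `or`, `ci_low`, `ci_high`, `pval`, `tier` (`significant`,
#'   `suggestive`, `null`, or `skipped`), concordance labels `egger_label` /
#'   `wme_label` / `mbe_label`, `het_stat`, `het_pval`,
#'   `steiger_direction`, `power`, and `note` for skips.
#' @examples
#' sims <- lapply(1:2, function(i) {
#'   simulate_two_sample(sim_truth(beta_causal = 0.2 * (i - 1), seed = i))
#' })
#' cfg <- analysis_config(
#'   exposures = list(null_trait = sims[[1]]$exposure,
#'                    causal_trait = sims[[2]]$exposure),
#'   outcome_studies = sims[[2]]$outcome, n_boot = 50, seed = 99)
#' run_study(cfg)
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  outcome_list <- purrr::map(cfg$outcome_studies, resolve_dataset)
  outcome <- if (length(outcome_list) > 1) {
    meta_fixed(outcome_list)
  } else {
    outcome_list[[1]]
  }
  out_meta <- gwas_trait(outcome)
  thr <- bonferroni_thresholds(cfg$alpha, length(cfg$exposures))

  rows <- purrr::imap(cfg$exposures, function(exp_raw, name) {
    seed_i <- child_seed(cfg$seed, match(name, names(cfg$exposures)))
    skip_row <- function(note) {
      tibble(risk_factor = name, subtype = cfg$subtype,
             n_snp = NA_integer_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pval = NA_real_, tier = "skipped",
             egger_label = NA_character_, wme_label = NA_character_,
             mbe_label = NA_character_, het_stat = NA_real_,
             het_pval = NA_real_, steiger_direction = NA_character_,
             power = NA_real_, note = note)
    }
    tryCatch({
      exposure <- resolve_dataset(exp_raw)
      instrument <- select_instruments(exposure,
                                       p_threshold = cfg$p_instrument)
      if (nrow(instrument) == 0) {
        return(skip_row("no genome-wide significant SNPs"))
      }
      instrument <- if (is.null(cfg$ld)) {
        suppressWarnings(clump(instrument, ld = NULL,
                               r2_threshold = cfg$r2_clump))
      } else {
        clump(instrument, ld = cfg$ld, r2_threshold = cfg$r2_clump)
      }
      hs <- harmonize(instrument, outcome)
      pairs <- kept_pairs(hs)
      if (nrow(pairs) == 0) {
        return(skip_row("no harmonizable SNPs in outcome"))
      }

      ivw <- mr_ivw(hs)
      exp_meta <- gwas_trait(exposure)
      ivw_or <- to_odds_ratio(ivw, exp_meta)
      tier <- if (ivw$pval < thr$strict) {
        "significant"
      } else if (ivw$pval < 0.05) {
        "suggestive"
      } else {
        "null"
      }

      r2_ins <- variance_explained(
        dplyr::rename(pairs, beta = "beta_exp", se = "se_exp"),
        n = if (!is.null(exp_meta)) exp_meta$n_total else pairs$n)
      pw <- mr_power(
        n_outcome = if (!is.null(out_meta)) out_meta$n_total else
          max(outcome$n),
        case_fraction = if (!is.null(out_meta)) out_meta$case_fraction else
          NULL,
        r2_instrument = r2_ins, beta_target = ivw$beta, alpha = 0.05)

      labels <- c(egger = NA_character_, wme = NA_character_,
                  mbe = NA_character_)
      het_stat <- het_pval <- NA_real_
      steiger_dir <- NA_character_
      if (tier != "null" || isTRUE(cfg$sensitivity_all)) {
        rep <- suppressMessages(
          sensitivity_report(hs, alpha = 0.05, n_boot = cfg$n_boot,
                             seed = seed_i))
        labels <- rep$concordance
        if (!is.null(rep$q)) {
          het_stat <- rep$q$q
          het_pval <- rep$q$pval
        }
        if (!is.null(rep$steiger)) steiger_dir <- rep$steiger$direction
      }

      tibble(risk_factor = name, subtype = cfg$subtype,
             n_snp = ivw$n_snp, or = ivw_or$or, ci_low = ivw_or$or_ci_low,
             ci_high = ivw_or$or_ci_high, pval = ivw$pval, tier = tier,
             egger_label = labels[["egger"]], wme_label = labels[["wme"]],
             mbe_label = labels[["mbe"]], het_stat = het_stat,
             het_pval = het_pval, steiger_direction = steiger_dir,
             power = pw$power, note = NA_character_)
    }, error = function(e) skip_row(conditionMessage(e)))
  })

  out <- purrr::list_rbind(rows) |>
    dplyr::arrange(.data$tier == "skipped", .data$pval)
  attr(out, "thresholds") <- thr
  class(out) <- unique(c("results_rows", class(out)))
  out
}

RESULTS_COLUMNS <- c("risk_factor", "subtype", "or", "ci_low", "ci_high",
                     "pval", "egger_label", "wme_label", "mbe_label",
                     "het_stat", "het_pval", "steiger_direction", "power",
                     "n_snp", "tier")

#' Render a study results table
#'
#' Produces the standard results layout — risk factor, subtype, OR with 95%
#' CI, IVW p-value, the three concordance labels, heterogeneity, Steiger
#' direction, power — as an aligned plain-text report, optionally writing a
#' machine-readable TSV with the same fixed column order
#' (`tidymr:::RESULTS_COLUMNS`).
#'
#' @param rows A [run_study()] result (or any tibble with the same
#'   columns).
#' @param tsv Optional path; when given, the TSV rendering is written
#'   there.
#' @return The aligned-text rendering as a character vector of lines
#'   (header first).
#' @export
render_table <- function(rows, tsv = NULL) {
  tbl <- as_tibble(rows)[RESULTS_COLUMNS]
  if (!is.null(tsv)) {
    readr::write_tsv(tbl, tsv, progress = FALSE)
  }
  fmt <- dplyr::mutate(
    tbl,
    or = sprintf("%.2f", .data$or),
    ci = sprintf("%.2f to %.2f", .data$ci_low, .data$ci_high),
    pval = sprintf("%.3g", .data$pval),
    het = ifelse(is.na(.data$het_stat), "NA",
                 sprintf("%.2f (%.3g)", .data$het_stat, .data$het_pval)),
    power = sprintf("%.2f", .data$power)
  )[c("risk_factor", "subtype", "or", "ci", "pval", "egger_label",
      "wme_label", "mbe_label", "het", "power", "tier")]
  fmt <- dplyr::mutate(fmt, dplyr::across(
    dplyr::everything(), ~ ifelse(is.na(.x), "NA", as.character(.x))))
  names(fmt) <- c("Risk factor", "Subtype", "OR", "95% CI", "P value",
                  "MR Egger", "WME", "MBE", "Heterogeneity (P)", "Power",
                  "Tier")
  widths <- pmax(nchar(names(fmt)),
                 purrr::map_int(fmt, ~ max(nchar(.x), 0L)))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(purrr::map2_chr(names(fmt), widths, pad), collapse = "  ")
  body <- purrr::pmap_chr(fmt, function(...) {
    paste(purrr::map2_chr(as.character(c(...)), widths, pad),
          collapse = "  ")
  })
  c(header, body)
}
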