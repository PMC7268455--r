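#' Case-control composition of the glioma outcome GWAS the defaults emulate
#'
#' The default outcome scenario of [sim_truth()] emulates a glioma
#' case-control GWAS pooled over two consortia — the Glioma International
#' Case-Control study (GICC) and the University of Texas MD Anderson Cancer
#' Center study (MDA) — analysed for all glioma and for the glioblastoma
#' (GBM) and non-glioblastoma subtypes. This table records that composition;
#' pooling the per-consortium case counts yields the subtype totals (5739
#' all glioma, 3112 GBM, 2411 non-GBM) used in the package defaults. The
#' GICC control count is reported inconsistently at source (3256 in the
#' pooled description, 3265 in the subtype breakdown); both appear here
#' as printed.
#'
#' @return A tibble with columns `subtype` (`"all_glioma"`, `"gbm"`,
#'   `"non_gbm"`), `consortium` (`"GICC"`, `"MDA"`), `cases`, `controls`.
#' @examples
#' dplyr::count(glioma_study_sizes(), subtype, wt = cases)
#' @export
glioma_study_sizes <- function() {
  tibble(
    subtype = rep(c("all_glioma", "gbm", "non_gbm"), each = 2),
    consortium = rep(c("GICC", "MDA"), times = 3),
    cases = c(4564, 1175, 2460, 652, 1898, 513),
    controls = c(3256, 2236, 3265, 2236, 3265, 2236)
  )
}
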