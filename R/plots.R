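# ggplot2 views of the analysis objects. All plot functions return a
# ggplot so callers can restyle them.

#' Scatter plot of a harmonized set with estimator fits
#'
#' Instrument-exposure effects against instrument-outcome effects with
#' per-SNP error bars; one fitted line per supplied estimator (through the
#' origin for IVW-family methods, with intercept for Egger).
#'
#' @param object An [harmonize()] result.
#' @param results Optional stacked `mr_result` tibble (e.g. from
#'   [mr_all()]) to draw fitted lines for.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_harmonized <- function(object, results = NULL, ...) {
  pairs <- kept_pairs(object)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$beta_exp,
                                           y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out -
                                          .data$se_out,
                                        ymax = .data$beta_out +
                                          .data$se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp -
                                           .data$se_exp,
                                         xmax = .data$beta_exp +
                                           .data$se_exp),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome (log odds)") +
    ggplot2::theme_minimal()
  if (!is.null(results) && nrow(results) > 0) {
    lines <- tibble(
      method = results$method,
      slope = results$beta,
      intercept = if ("intercept" %in% names(results)) {
        ifelse(is.na(results$intercept), 0, results$intercept)
      } else {
        0
      }
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' Radial MR plot
#'
#' Plots each SNP's precision-scaled ratio (`ratio * sqrt(w)`) against its
#' precision (`sqrt(w)`); the slope of the line through the origin is the
#' fixed-effects IVW estimate, and flagged heterogeneity outliers are
#' highlighted.
#'
#' @param object A [radial_ivw()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_radial <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$outlier)) +
    ggplot2::geom_abline(slope = object$result$beta, intercept = 0,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(sqrt(w[j])),
                  y = expression(hat(beta)[j] * sqrt(w[j])),
                  colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Leave-one-out forest plot
#'
#' One row per omitted SNP, showing the re-estimated IVW effect and its 95%
#' confidence interval, with the full-sample estimate as a reference line.
#'
#' @param loo A [leave_one_out()] result.
#' @param full Optional full-sample `mr_result` for the reference line.
#' @return A ggplot.
#' @export
plot_leave_one_out <- function(loo, full = NULL) {
  p <- ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta,
                                         y = .data$snp_omitted)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting SNP (log odds)",
                  y = "omitted SNP") +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(xintercept = full$beta,
                                 linetype = "dashed", colour = "steelblue")
  }
  p
}
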