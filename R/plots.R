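#' Forest plot of observed-scale rate ratios
#'
#' One point per stratum-test with its exact 95% CI, on a log ratio axis,
#' faceted by inheritance mode; the dashed line marks the null ratio 1.
#'
#' @param results A results table from [burden_test()] or
#'   [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_burden <- function(results) {
  df <- as_tibble(results) %>%
    filter(is.finite(.data$ratio), .data$ratio > 0) %>%
    mutate(stratum = paste(.data$sex, .data$phenotype_group,
                           .data$variant_class, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low,
                   xmax = pmin(.data$ci_high, max(.data$ratio) * 4)),
      height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~mode, scales = "free_x") +
    ggplot2::labs(x = "rate ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of liability-scale effect sizes
#'
#' @param results A [run_pipeline()] results table carrying `z`, `z_ci_low`
#'   and `z_ci_high` columns.
#' @return A ggplot object.
#' @export
plot_liability <- function(results) {
  df <- as_tibble(results) %>%
    filter(!is.na(.data$z)) %>%
    mutate(stratum = paste(.data$sex, .data$phenotype_group,
                           .data$variant_class, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$z_ci_low, xmax = .data$z_ci_high),
      height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex), size = 2) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "liability effect size (SD units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.varliab_pipeline <- function(object, ...) {
  plot_liability(object$results)
}

#' Liability distribution of a simulated cohort
#'
#' Histogram of the latent liabilities of probands and siblings by sex,
#' with the sex-specific diagnostic thresholds overlaid -- a visual check
#' that ascertainment truncates probands above their thresholds.
#'
#' @param object A `simulated_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.simulated_cohort <- function(object, ...) {
  li <- object$truth$liabilities
  th <- object$truth$thresholds
  ggplot2::ggplot(li, ggplot2::aes(x = .data$liability, fill = .data$role)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(data = th,
                        ggplot2::aes(xintercept = .data$autism_threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "latent liability (SD units)", y = "children") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
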