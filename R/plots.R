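# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-response fit
#'
#' Observed points with the fitted curve on a log concentration axis.
#'
#' @param object A `dose_fit`.
#' @param n Points in the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_fit <- function(object, n = 200, ...) {
  data <- object$data
  xpos <- data$effector_uM[data$effector_uM > 0]
  grid <- tibble::tibble(
    effector_uM = 10^seq(log10(min(xpos)), log10(max(xpos)), length.out = n))
  grid$rate <- predict(object, grid)
  ggplot2::ggplot(dplyr::filter(data, .data$effector_uM > 0),
                  ggplot2::aes(.data$effector_uM, .data$rate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[effector] (µM)", y = "rate",
                  title = sprintf("%s fit (R² = %.3f)", object$model,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a MIMS trace as log enrichment over time
#'
#' Log 18O atom-fraction enrichment against time with reagent-addition
#' events marked; the per-segment slopes of this display are the assay's
#' activity statistic.
#'
#' @param object A [mims_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mims_trace <- function(object, ...) {
  series <- atom_fraction_enrichment(object)
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(.data$time_min, log(.data$enrichment))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "ln(atom fraction enrichment)") +
    ggplot2::theme_minimal()
  if (length(object$events) > 0) {
    ev <- tibble::tibble(label = names(object$events),
                         time_min = unname(object$events))
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time_min),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot regulated vs unregulated sweep outputs
#'
#' Faceted comparison of net CA flux, effective carboxylation turnover
#' and luminal pH against external RuBP for the regulated and
#' unregulated models.
#'
#' @param regulated,unregulated Sweep tibbles from [run_rubp_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(regulated, unregulated) {
  both <- dplyr::bind_rows(
    dplyr::mutate(regulated, model = "RuBP-regulated CA"),
    dplyr::mutate(unregulated, model = "constitutive CA"))
  long <- tidyr::pivot_longer(
    dplyr::select(both, "rubp_mM", "model", "ca_flux_mM_s",
                  "kcat_c_eff_s", "ph_cbx"),
    cols = c("ca_flux_mM_s", "kcat_c_eff_s", "ph_cbx"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$rubp_mM, .data$value,
                                     colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          ca_flux_mM_s = "net CA dehydration flux (mM/s)",
                          kcat_c_eff_s = "effective kcatC (1/s per site)",
                          ph_cbx = "carboxysomal pH"))) +
    ggplot2::labs(x = "external RuBP (mM)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
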