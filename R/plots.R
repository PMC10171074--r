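# Thin ggplot2 layer over the result tables.

#' Plot a learning curve
#'
#' Mean stratified RMSE versus training-set size, one panel per stratum,
#' error bars one standard deviation across seeds.
#'
#' @param object A [learning_curve()] table.
#' @param strata Which strata to show (default localized + delocalized).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_curve <- function(object,
                                    strata = c("localized", "delocalized"),
                                    ...) {
  sm <- summarise_learning_curve(object)
  sm <- filter(sm, .data$stratum %in% strata)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$size, y = .data$mean_rmse,
                                   colour = .data$head)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rmse - .data$sd_rmse,
      ymax = .data$mean_rmse + .data$sd_rmse), width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "training set size", y = "RMSE (eV)",
                  colour = "pooling")
}

#' Histogram of weight-fraction correlations
#'
#' Distribution of per-molecule Pearson correlations between learned weights
#' and reference localization fractions, optionally split by stratum.
#'
#' @param correlations Output of [weight_correlations()] (optionally with an
#'   extra `head` column to facet several models).
#' @param localized_cut,delocalized_cut Stratum thresholds.
#' @return A ggplot object.
#' @export
plot_weight_correlations <- function(correlations, localized_cut = 0.8,
                                     delocalized_cut = 0.4) {
  dat <- mutate(as_tibble(correlations),
                stratum = dplyr::case_when(
                  .data$L >= localized_cut ~ "localized",
                  .data$L < delocalized_cut ~ "delocalized",
                  TRUE ~ "middle"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pearson_r)) +
    ggplot2::geom_histogram(bins = 30, boundary = 1) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Pearson R (weights vs l_i)", y = "molecules")
  if ("head" %in% names(dat)) {
    p <- p + ggplot2::aes(fill = .data$head)
  }
  p
}

#' Plot the localization-index distribution of a dataset
#'
#' @param dataset An `orb_dataset` with `L` values.
#' @param localized_cut,delocalized_cut Thresholds drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_L_distribution <- function(dataset, localized_cut = 0.8,
                                delocalized_cut = 0.4) {
  ggplot2::ggplot(tibble(L = dataset$L), ggplot2::aes(x = .data$L)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(delocalized_cut, localized_cut),
                        linetype = "dashed") +
    ggplot2::labs(x = "localization index L", y = "molecules")
}
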