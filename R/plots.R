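#' Plot a deflation report
#'
#' Bar chart of every observed and corrected estimator of a
#' [deflation_report()], in the spirit of estimator-comparison figures:
#' deflation-prone estimators (pmc, eta, tau-b) fall visibly short of the
#' deflation-robust ones (gamma, Somers delta g-given-X, r_ac, e_ac) when
#' the scales of the pair differ.
#'
#' @param object A `deflation_report`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.deflation_report <- function(object, ...) {
  d <- tidy(object)
  d$label <- ifelse(d$direction %in% c("not_applicable", "symmetric"),
    d$estimator, paste0(d$estimator, " (", d$direction, ")"))
  d$label <- factor(d$label, levels = rev(unique(d$label)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$label,
      fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "estimate", y = NULL, fill = NULL,
      title = "Observed vs margin-corrected association estimates") +
    ggplot2::theme_minimal()
}

#' Mean estimates by item scale width
#'
#' Line chart of the mean `rit`, `eta1` and `eta2` of an item table against
#' the item degrees of freedom `df_g`: the three curves converge as the item
#' scale widens, visualising how directionality fades with narrowing scale
#' discrepancy.
#'
#' @param rows An item table from [item_analysis_table()] or
#'   [collection_item_table()].
#' @param df_g_top Pool `df_g >= df_g_top` (default 13).
#' @returns A ggplot object.
#' @export
plot_estimates_by_categories <- function(rows, df_g_top = 13L) {
  stopifnot(is.data.frame(rows))
  d <- rows |>
    dplyr::filter(!is.na(.data$diff)) |>
    dplyr::mutate(df_g = pmin(.data$df_g, df_g_top)) |>
    dplyr::group_by(.data$df_g) |>
    dplyr::summarise(rit = mean(.data$rit), eta1 = mean(.data$eta1),
      eta2 = mean(.data$eta2), .groups = "drop") |>
    tidyr::pivot_longer(c("rit", "eta1", "eta2"), names_to = "estimator",
      values_to = "mean_estimate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$df_g, y = .data$mean_estimate,
      colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "item degrees of freedom df(g)",
      y = "mean estimate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Directionality gap across bins
#'
#' Point-and-line chart of a [binned_difference_summary()]: the mean
#' `eta2 - eta1` per bin, with one standard deviation shown as a ribbon.
#'
#' @param summary A `binned_summary`.
#' @returns A ggplot object.
#' @export
plot_difference_by_bins <- function(summary) {
  stopifnot(inherits(summary, "binned_summary"))
  d <- as_tibble(summary)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_index, y = .data$mean_diff)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_diff - .data$sd_diff,
      ymax = .data$mean_diff + .data$sd_diff), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$bin_index, labels = d$bin) +
    ggplot2::labs(x = attr(summary, "by"), y = "mean eta2 - eta1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
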