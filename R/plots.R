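#' Waterfall plot of Shapley attributions
#'
#' Bars rise (or fall) from the empty-coalition value 0.5 through each
#' player's contribution, ending at the full-coalition AUROC. Players are
#' drawn in descending `phi` order.
#'
#' @param object an `ehrf_attribution`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ehrf_attribution
#' @export
autoplot.ehrf_attribution <- function(object, ...) {
  d <- tidy(object)
  d <- d[order(-d$phi), ]
  d$v_cum <- attr(object, "v_empty") + cumsum(d$phi)
  d$start <- c(attr(object, "v_empty"), utils::head(d$v_cum, -1))
  d$player <- factor(d$source, levels = d$source)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$player)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(.data$player) - 0.4,
      xmax = as.numeric(.data$player) + 0.4,
      ymin = .data$start, ymax = .data$v_cum,
      fill = .data$phi >= 0), show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "v_empty"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "AUROC",
                  title = "Shapley attribution waterfall") +
    ggplot2::theme_minimal()
}

#' Heatmap of mean AUROC by modality and source counts
#'
#' The classic ablation grid: cells are (number of modalities, number of
#' sources) groups; fill is the group's mean test AUROC.
#'
#' @param object an `ehrf_auroc_summary` from [summarize_auroc()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ehrf_auroc_summary
#' @export
autoplot.ehrf_auroc_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_cell,
                  ggplot2::aes(x = factor(.data$n_sources),
                               y = factor(.data$n_modalities),
                               fill = .data$auroc_mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$auroc_mean)), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Number of sources", y = "Number of modalities",
                  fill = "Mean AUROC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
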