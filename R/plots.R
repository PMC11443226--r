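#' Plot organ growth trajectories of a season
#'
#' Final-state organ sizes by kind and rank for the interior plants: leaf
#' lengths by rank, scape length and the bud length distribution.
#'
#' @param object A `hemsim_season` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemsim_season <- function(object, ...) {
  org <- object$organs[object$organs$interior, ]
  ggplot2::ggplot(org, ggplot2::aes(x = .data$rank, y = .data$length_m)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.3, size = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "darkgreen") +
    ggplot2::facet_wrap(~organ, scales = "free") +
    ggplot2::labs(x = "organ rank", y = "final length (m)",
                  title = "Final organ sizes (interior plants)")
}

#' Plot the daily canopy fluxes of a season
#'
#' Daily mean per-leaf absorbed PPFD and net assimilation over the season.
#'
#' @param season A `hemsim_season` object.
#' @return A ggplot.
#' @export
plot_canopy_fluxes <- function(season) {
  cn <- tidyr::pivot_longer(
    season$canopy[, c("day", "ppfd_mean", "anet_mean")],
    -"day", names_to = "flux", values_to = "value"
  )
  ggplot2::ggplot(cn, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~flux, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          ppfd_mean = "absorbed PPFD (umol m-2 s-1)",
                          anet_mean = "net assimilation (umol m-2 s-1)"))) +
    ggplot2::labs(x = "day of year", y = NULL)
}

#' Plot a sweep summary
#'
#' Per-hectare yield against mean bud length for every scenario, with the
#' dual selection thresholds.
#'
#' @param object A `hemsim_sweep` tibble.
#' @param bud_length_min,yield_min Selection thresholds drawn as reference
#'   lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemsim_sweep <- function(object, bud_length_min = 0.12,
                                  yield_min = 35, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_bud_len_m, y = .data$yield_t_ha,
                               colour = .data$pattern)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), vjust = -0.7,
                       size = 3, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = bud_length_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = yield_min, linetype = 2) +
    ggplot2::labs(x = "mean bud length (m)", y = "bud yield (t/ha)",
                  colour = "pattern")
}

#' Plot PLS-PM path coefficients
#'
#' Standardized direct path estimates of a fitted PLS path model.
#'
#' @param object A `hemsim_plspm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemsim_plspm <- function(object, ...) {
  pt <- object$paths
  pt$label <- paste(pt$from, "->", pt$to)
  ggplot2::ggplot(pt, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "standardized path coefficient")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
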