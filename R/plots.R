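#' Isotope biplot of sources and consumers
#'
#' The standard d13C-d15N mixing-space plot: source means with +/- 1 sigma
#' error bars (optionally TDF-shifted into consumer space) and consumer
#' tissue values. Consumers falling outside the TDF-shifted source range
#' cannot be explained as a convex mixture.
#'
#' @param problem A [mixing_problem()].
#' @param shift_sources Shift sources by each guild's TDF mean (one panel
#'   per guild present among the consumers) rather than plotting raw source
#'   values.
#' @return A ggplot object.
#' @export
plot_mixing_space <- function(problem, shift_sources = TRUE) {
  stopifnot(inherits(problem, "mixing_problem"))
  src <- problem$sources
  cons <- problem$consumers
  if (shift_sources) {
    guilds <- unique(cons$guild)
    src <- purrr::map_dfr(guilds, function(g) {
      tdf <- tdf_for_guild(problem$tdf, g)
      dplyr::mutate(src, guild = g,
                    d13c_mean = .data$d13c_mean + tdf$mean[1],
                    d15n_mean = .data$d15n_mean + tdf$mean[2])
    })
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_errorbar(
      data = src,
      ggplot2::aes(x = .data$d13c_mean,
                   ymin = .data$d15n_mean - .data$d15n_sd,
                   ymax = .data$d15n_mean + .data$d15n_sd,
                   colour = .data$name),
      width = 0
    ) +
    ggplot2::geom_errorbarh(
      data = src,
      ggplot2::aes(y = .data$d15n_mean,
                   xmin = .data$d13c_mean - .data$d13c_sd,
                   xmax = .data$d13c_mean + .data$d13c_sd,
                   colour = .data$name),
      height = 0
    ) +
    ggplot2::geom_point(
      data = src,
      ggplot2::aes(x = .data$d13c_mean, y = .data$d15n_mean,
                   colour = .data$name),
      shape = 15, size = 3
    ) +
    ggplot2::geom_point(
      data = cons,
      ggplot2::aes(x = .data$d13c, y = .data$d15n),
      shape = 21, size = 2.5, fill = "grey30"
    ) +
    ggplot2::labs(
      x = expression(delta^13 * C ~ "(‰)"),
      y = expression(delta^15 * N ~ "(‰)"),
      colour = if (shift_sources) "source (+TDF)" else "source"
    ) +
    ggplot2::theme_minimal()
  if (shift_sources && length(unique(cons$guild)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$guild))
  }
  p
}

#' Posterior diet-proportion plot
#'
#' Violin-and-interval display of the posterior diet proportions, one panel
#' per consumer.
#'
#' @param object A `mixing_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixing_fit
#' @export
autoplot.mixing_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$source, y = .data$proportion)) +
    ggplot2::geom_violin(fill = "grey80", colour = NA, scale = "width") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::stat_summary(
      fun.min = function(x) stats::quantile(x, 0.025),
      fun.max = function(x) stats::quantile(x, 0.975),
      geom = "linerange"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$id)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "diet proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Recovery-experiment plot
#'
#' Posterior means with 95% credible intervals against the known true
#' proportions; the identity line marks perfect recovery.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$per_consumer,
                  ggplot2::aes(x = .data$true, y = .data$mean,
                               colour = .data$source)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$conf.low,
                                         ymax = .data$conf.high),
                            alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true proportion", y = "posterior mean (95% CI)") +
    ggplot2::theme_minimal()
}
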