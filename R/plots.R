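#' Scatter plot of per-cell carbon vs nitrogen isotope ratios
#'
#' One dot per cell, colored by incubation time point, with the
#' natural-abundance baselines drawn as red reference lines. Cells near
#' the crossing of the red lines are unlabeled; spread away from it
#' indicates isotope uptake, and widening scatter indicates growing
#' cell-to-cell heterogeneity.
#'
#' @param measurements Measurement tibble with `R13`, `R15`, `timepoint_h`.
#' @param natural A [natural_abundance()] baseline.
#' @return A ggplot object.
#' @export
plot_isotope_scatter <- function(measurements, natural = natural_abundance()) {
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data$R13, y = .data$R15,
                               colour = factor(.data$timepoint_h))) +
    ggplot2::geom_vline(xintercept = natural$R13, colour = "red",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = natural$R15, colour = "red",
                        linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::labs(x = "13C-/12C- ratio", y = "15N/14N ratio",
                  colour = "hpi") +
    ggplot2::theme_minimal()
}

#' Plot a variable's time course with the fitted trend
#'
#' Per-cell values as jittered dots, per-time-point medians as bars, and
#' the modal bootstrap polynomial as a dashed curve.
#'
#' @param object A `nanosip_bootfit`.
#' @param data Optional measurement tibble to overdraw the raw cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nanosip_bootfit
#' @export
autoplot.nanosip_bootfit <- function(object, data = NULL, ...) {
  med <- tibble(timepoint_h = object$times, value = object$medians)
  grid <- tibble(timepoint_h = seq(min(object$times), max(object$times),
                                   length.out = 200))
  grid$value <- predict(object, grid)
  p <- ggplot2::ggplot(med, ggplot2::aes(x = .data$timepoint_h, y = .data$value))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_jitter(
      data = tibble(timepoint_h = data$timepoint_h,
                    value = data[[object$variable]]),
      width = 0.15, alpha = 0.35, size = 1, colour = "grey40")
  }
  p +
    ggplot2::geom_point(shape = 95, size = 8) +
    ggplot2::geom_line(data = grid, linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "hours post-incubation", y = object$variable,
                  title = sprintf("Modal polynomial fit (RSS = %.4g)", object$rss)) +
    ggplot2::theme_minimal()
}

#' Histograms of bootstrap coefficient distributions
#'
#' @param fit A `nanosip_bootfit`.
#' @return A ggplot object, one facet per polynomial coefficient, with
#'   the modal (reported) value marked.
#' @export
plot_coefficient_histograms <- function(fit) {
  stopifnot(inherits(fit, "nanosip_bootfit"))
  tbl <- purrr::imap_dfr(fit$histograms, function(h, term)
    dplyr::mutate(h, term = term))
  modal <- tibble(term = names(fit$coefficients),
                  value = unname(fit$coefficients))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = NA, fill = "steelblue") +
    ggplot2::geom_vline(data = modal, ggplot2::aes(xintercept = .data$value),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "coefficient value", y = "replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
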