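#' Per-time-point heterogeneity profile
#'
#' Quantifies how the cell-to-cell dispersion of a variable evolves over
#' incubation: per time point the interquartile range (IQR), the
#' median-normalized IQR (a robust coefficient of variation), and n; the
#' overall trend is summarized as the Spearman rank correlation of IQR
#' with time. Increasing dispersion indicates growing metabolic
#' heterogeneity among cells.
#'
#' @param data Tibble with columns `timepoint_h` and the chosen variable.
#' @param variable Column to profile.
#' @param min_n Time points with fewer values are flagged (not dropped).
#' @return A tibble (class `nanosip_heterogeneity`) with columns
#'   `timepoint_h`, `n`, `median`, `iqr`, `rcv`, `flag`; the trend is in
#'   attributes `spearman_rho` and `trend_flag` (also shown by `print()`),
#'   or via [heterogeneity_trend()].
#' @export
heterogeneity_profile <- function(data, variable = "R13", min_n = 3) {
  data <- as_tibble(data)
  if (!variable %in% names(data))
    abort(sprintf("Column %s not found.", variable))
  prof <- data |>
    dplyr::group_by(.data$timepoint_h) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[variable]]),
      iqr = IQR(.data[[variable]]),
      .groups = "drop") |>
    dplyr::arrange(.data$timepoint_h) |>
    dplyr::mutate(
      rcv = ifelse(.data$median != 0, .data$iqr / abs(.data$median), NA_real_),
      flag = ifelse(.data$n < min_n, "undersized", ""))

  usable <- prof$flag == ""
  trend_flag <- ""
  if (sum(usable) < 2 || sd(prof$iqr[usable]) == 0 ||
      sd(prof$timepoint_h[usable]) == 0) {
    rho <- 0
    trend_flag <- "trend undefined (constant or insufficient IQRs); reported as 0"
  } else {
    rho <- cor(prof$timepoint_h[usable], prof$iqr[usable], method = "spearman")
  }
  structure(prof, spearman_rho = rho, trend_flag = trend_flag,
            variable = variable,
            class = c("nanosip_heterogeneity", class(prof)))
}

#' Extract the heterogeneity trend
#'
#' @param profile A [heterogeneity_profile()] result.
#' @return One-row tibble: `variable`, `spearman_rho`, `flag`.
#' @export
heterogeneity_trend <- function(profile) {
  tibble(variable = attr(profile, "variable"),
         spearman_rho = attr(profile, "spearman_rho"),
         flag = attr(profile, "trend_flag"))
}

#' @export
print.nanosip_heterogeneity <- function(x, ...) {
  NextMethod()
  cat(sprintf("Spearman(IQR, time) = %.3f%s\n", attr(x, "spearman_rho"),
              if (nzchar(attr(x, "trend_flag")))
                paste0(" [", attr(x, "trend_flag"), "]") else ""))
  invisible(x)
}
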