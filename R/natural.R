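#' Natural-abundance isotope ratio baselines
#'
#' Environmental baseline secondary-ion count ratios used as the zero point
#' for enrichment: 0.0112 for 13C-/12C- and 0.0037 for 15N/14N (the latter
#' measured via the 12C15N-/12C14N- ratio). Both may be overridden, e.g. for
#' instruments with different relative sensitivity factors.
#'
#' @param R13 Natural 13C-/12C- count ratio.
#' @param R15 Natural 15N/14N count ratio (via 12C15N-/12C14N-).
#' @return A list with elements `R13`, `R15` and the corresponding atom
#'   fractions `F13`, `F15` (F = R / (1 + R)).
#' @export
natural_abundance <- function(R13 = 0.0112, R15 = 0.0037) {
  if (!is.numeric(R13) || length(R13) != 1L || R13 <= 0)
    abort("`R13` must be a single positive number.")
  if (!is.numeric(R15) || length(R15) != 1L || R15 <= 0)
    abort("`R15` must be a single positive number.")
  structure(
    list(R13 = R13, R15 = R15,
         F13 = R13 / (1 + R13), F15 = R15 / (1 + R15)),
    class = "nanosip_natural"
  )
}

#' @export
print.nanosip_natural <- function(x, ...) {
  cat(sprintf("Natural abundance: R13 = %.4g (F13 = %.5g), R15 = %.4g (F15 = %.5g)\n",
              x$R13, x$F13, x$R15, x$F15))
  invisible(x)
}

ratio_to_fraction <- function(R) R / (1 + R)
fraction_to_ratio <- function(F) F / (1 - F)
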