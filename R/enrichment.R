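#' Draw per-cell atom fractions along a quadratic median trajectory
#'
#' The population median atom fraction at time `t` is
#' `c2 t^2 + c1 t + c0`; individual cells scatter around it with standard
#' deviation `spread` (normal draws, clipped to `[0, 1)`). With
#' `spread = 0` every cell sits exactly on the trajectory.
#'
#' @param timepoint_h Incubation time in hours (>= 0).
#' @param coeffs Length-3 numeric `(c2, c1, c0)`.
#' @param spread Cell-to-cell SD of the atom fraction (>= 0).
#' @param n_cells Number of cells to draw.
#' @param seed Optional seed for reproducible draws.
#' @return Numeric vector of `n_cells` atom fractions in `[0, 1)`.
#' @export
enrichment_trajectory <- function(timepoint_h, coeffs, spread, n_cells,
                                  seed = NULL) {
  if (timepoint_h < 0) abort("`timepoint_h` must be >= 0.")
  if (length(coeffs) != 3L || !is.numeric(coeffs))
    abort("`coeffs` must be numeric (c2, c1, c0).")
  if (!is.numeric(spread) || length(spread) != 1L || spread < 0)
    abort("`spread` must be a single non-negative number.")
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  center <- coeffs[1] * timepoint_h^2 + coeffs[2] * timepoint_h + coeffs[3]
  draw <- function() {
    x <- if (spread == 0) rep(center, n_cells) else rnorm(n_cells, center, spread)
    pmin(pmax(x, 0), 1 - 1e-9)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
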