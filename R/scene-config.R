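#' Configure a synthetic NanoSIMS scene
#'
#' Describes a field of rod-shaped cells imaged as multi-plane secondary-ion
#' count stacks. The defaults emulate the acquisition this package targets:
#' 256 x 256 pixel rasters, six planes per ion, six ions acquired in
#' parallel (12C-, 13C-, 12C14N-, 12C15N-, 16O-, 32S-), rods of roughly
#' 5 um x 1 um, and isotope channels at natural abundance (an unlabeled
#' control scene). Labeling experiments are described by
#' `enrich_median_coeffs` (the quadratic-in-time median atom-fraction
#' trajectory) and `enrich_spread` (cell-to-cell standard deviation,
#' non-decreasing in time); see [study_enrichment()] for a ready-made
#' labeled parameterization.
#'
#' @param n_cells Number of rod cells to place (0 gives a pure-background
#'   scene).
#' @param image_size Pixels per side of the square raster.
#' @param raster_um Physical field width in micrometres (instrument range
#'   5-41 um).
#' @param n_planes Number of consecutively captured planes per ion.
#' @param cell_length_um,cell_width_um Length-2 ranges from which rod length
#'   and width are drawn uniformly; width is capped at length.
#' @param base_rate Named vector of expected in-cell counts per pixel per
#'   plane for ions 12C, 13C, 12C14N, 12C15N and 16O. The isotope entries
#'   set the channel totals: per cell, the carbon total (12C + 13C) is
#'   re-split by that cell's 13C atom fraction, and likewise for nitrogen,
#'   so the defaults (rare/common = 0.0112 and 0.0037) describe natural
#'   abundance. 32S is derived, not listed: its expectation is
#'   `s32_factor` times the total CN expectation, encoding the observed
#'   colocalization of 32S- with 12C14N- signal.
#' @param bg_frac Background expectation as a fraction of the in-cell rate,
#'   applied per ion.
#' @param chain_o16_boost Multiplicative 16O- enrichment along a 1-px-wide
#'   stripe on each cell's major axis (the magnetosome chain; magnetite
#'   retains more 16O- than cytoplasm).
#' @param s32_factor Proportionality of the 32S- expectation to the total
#'   CN expectation.
#' @param enrich_median_coeffs List with elements `F13` and `F15`, each a
#'   length-3 vector `(c2, c1, c0)`: the median atom fraction at `t` hours
#'   is `c2 t^2 + c1 t + c0`.
#' @param enrich_spread List with elements `F13` and `F15` giving the
#'   cell-to-cell SD of the atom fraction as a function of time: either a
#'   length-2 vector `(base, per_hour)` (linear, slope >= 0), a named
#'   numeric vector tabulated by time point (non-decreasing), or a function
#'   of time.
#' @param drift_max_px Maximum absolute per-plane translational drift in
#'   pixels (plane 1 never drifts).
#' @param natural A [natural_abundance()] object.
#' @param seed Root seed; per-scene child streams are derived from
#'   `(seed, timepoint, replicate)` so scenes are independently
#'   reproducible.
#' @return A `nanosip_scene_config` list.
#' @seealso [generate_scene()], [study_enrichment()]
#' @export
scene_config <- function(n_cells = 5,
                         image_size = 256,
                         raster_um = 20,
                         n_planes = 6,
                         cell_length_um = c(4, 6.5),
                         cell_width_um = c(0.8, 1.2),
                         base_rate = NULL,
                         bg_frac = 0.01,
                         chain_o16_boost = 3,
                         s32_factor = 0.3,
                         enrich_median_coeffs = NULL,
                         enrich_spread = NULL,
                         drift_max_px = 3,
                         natural = natural_abundance(),
                         seed = 1L) {
  if (is.null(base_rate)) {
    base_rate <- c("12C" = 200, "13C" = 200 * natural$R13,
                   "12C14N" = 300, "12C15N" = 300 * natural$R15,
                   "16O" = 100)
  }
  needed <- c("12C", "13C", "12C14N", "12C15N", "16O")
  if (!all(needed %in% names(base_rate)))
    abort(paste0("`base_rate` must name ions: ",
                 paste(setdiff(needed, names(base_rate)), collapse = ", ")))
  if (any(base_rate < 0)) abort("All base rates must be >= 0.")
  if (bg_frac < 0 || s32_factor < 0 || chain_o16_boost < 0)
    abort("`bg_frac`, `s32_factor` and `chain_o16_boost` must be >= 0.")
  if (n_cells < 0 || image_size < 8 || n_planes < 1)
    abort("Invalid geometry: need n_cells >= 0, image_size >= 8, n_planes >= 1.")
  if (raster_um <= 0) abort("`raster_um` must be positive.")
  if (drift_max_px < 0) abort("`drift_max_px` must be >= 0.")
  stopifnot(length(cell_length_um) == 2L, length(cell_width_um) == 2L,
            all(cell_length_um > 0), all(cell_width_um > 0))

  if (is.null(enrich_median_coeffs)) {
    enrich_median_coeffs <- list(F13 = c(0, 0, natural$F13),
                                 F15 = c(0, 0, natural$F15))
  }
  if (is.null(enrich_spread)) {
    enrich_spread <- list(F13 = c(0, 0), F15 = c(0, 0))
  }
  for (iso in c("F13", "F15")) {
    co <- enrich_median_coeffs[[iso]]
    if (is.null(co) || length(co) != 3L)
      abort(sprintf("`enrich_median_coeffs$%s` must be (c2, c1, c0).", iso))
    validate_spread_spec(enrich_spread[[iso]], iso)
  }

  structure(
    list(n_cells = as.integer(n_cells), image_size = as.integer(image_size),
         raster_um = raster_um, n_planes = as.integer(n_planes),
         cell_length_um = cell_length_um, cell_width_um = cell_width_um,
         base_rate = base_rate[needed], bg_frac = bg_frac,
         chain_o16_boost = chain_o16_boost, s32_factor = s32_factor,
         enrich_median_coeffs = enrich_median_coeffs,
         enrich_spread = enrich_spread,
         drift_max_px = as.integer(drift_max_px),
         natural = natural, seed = as.integer(seed),
         pixel_um = raster_um / image_size, dwell_ms = 5),
    class = "nanosip_scene_config"
  )
}

validate_spread_spec <- function(sp, iso) {
  if (is.function(sp)) return(invisible(sp))
  if (!is.numeric(sp) || any(sp < 0))
    abort(sprintf("`enrich_spread$%s` must be non-negative.", iso))
  if (is.null(names(sp))) {
    if (length(sp) != 2L)
      abort(sprintf("`enrich_spread$%s` must be (base, per_hour), a tabulated named vector, or a function.", iso))
  } else {
    tp <- as.numeric(names(sp))
    if (anyNA(tp)) abort("Tabulated spread names must be numeric time points.")
    if (is.unsorted(sp[order(tp)]))
      abort(sprintf("Tabulated `enrich_spread$%s` must be non-decreasing in time.", iso))
  }
  invisible(sp)
}

spread_at <- function(sp, t) {
  if (is.function(sp)) return(sp(t))
  if (!is.null(names(sp))) {
    tp <- as.numeric(names(sp))
    i <- which(abs(tp - t) < 1e-9)
    if (length(i) != 1L)
      abort(sprintf("Time point %g h not in tabulated spread profile.", t))
    return(unname(sp[i]))
  }
  sp[1] + sp[2] * t
}

#' @export
print.nanosip_scene_config <- function(x, ...) {
  cat(sprintf("NanoSIMS scene config: %d cells, %dx%d px (%.3g um/px), %d planes, drift <= %d px, seed %d\n",
              x$n_cells, x$image_size, x$image_size, x$pixel_um,
              x$n_planes, x$drift_max_px, x$seed))
  invisible(x)
}

#' Enrichment parameters emulating the labeling study
#'
#' A ready-made labeled parameterization: 13C and 15N atom-fraction medians
#' follow a saturating quadratic in time starting from natural abundance,
#' and the cell-to-cell spread grows linearly with time (metabolic
#' heterogeneity increasing over incubation).
#'
#' @param natural A [natural_abundance()] object fixing the t = 0 baseline.
#' @return A list with `coeffs` and `spread`, suitable for
#'   `scene_config(enrich_median_coeffs = , enrich_spread = )`.
#' @export
study_enrichment <- function(natural = natural_abundance()) {
  list(
    coeffs = list(F13 = c(-4.5e-5, 2.1e-3, natural$F13),
                  F15 = c(-1.6e-5, 8e-4, natural$F15)),
    spread = list(F13 = c(5e-4, 4e-4), F15 = c(2e-4, 1.5e-4))
  )
}

# Deterministic child seed for a (root seed, timepoint, replicate) triple.
# Kept strictly below 2^31 so it is a valid R integer seed.
child_seed <- function(seed, timepoint_h, replicate = 1L) {
  mix <- (as.double(seed) * 1000003 +
            round(timepoint_h * 100) * 10007 +
            as.double(replicate) * 101) %% 2147483629
  as.integer(mix)
}
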