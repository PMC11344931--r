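# Shared fixtures: small, fast scene configurations used across test files.

# A compact scene: 64-px field, short rods, counts high enough for stable
# ratios but cheap to simulate.
small_config <- function(n_cells = 2, seed = 11, drift_max_px = 2, ...) {
  scene_config(n_cells = n_cells, image_size = 64, raster_um = 5,
               cell_length_um = c(1.8, 2.6), cell_width_um = c(0.5, 0.8),
               drift_max_px = drift_max_px, seed = seed, ...)
}

# Labeled variant with the study's enrichment model.
labeled_config <- function(n_cells = 3, seed = 21, ...) {
  en <- study_enrichment()
  small_config(n_cells = n_cells, seed = seed,
               enrich_median_coeffs = en$coeffs, enrich_spread = en$spread,
               ...)
}

# Brute-force drift oracle, independent of estimate_drift(): explicit double
# loop over the shift grid, correlation via cor() on explicitly constructed
# overlap windows.
oracle_drift <- function(ref, plane, max_shift) {
  n <- nrow(ref)
  best <- c(NA, NA); best_ncc <- -Inf; best_mag <- Inf
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      rs <- c(); as <- c(); bs <- c()
      r_lo <- max(1, 1 - dy); r_hi <- min(n, n - dy)
      c_lo <- max(1, 1 - dx); c_hi <- min(n, n - dx)
      if (r_hi <= r_lo || c_hi <= c_lo) next
      a <- ref[r_lo:r_hi, c_lo:c_hi]
      b <- plane[(r_lo:r_hi) + dy, (c_lo:c_hi) + dx]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      ncc <- stats::cor(as.vector(a), as.vector(b))
      mag <- dy^2 + dx^2
      if (ncc > best_ncc + 1e-12 ||
          (ncc > best_ncc - 1e-12 && mag < best_mag)) {
        best <- c(dy, dx); best_ncc <- ncc; best_mag <- mag
      }
    }
  }
  best
}

# Inject known integer drifts into a zero-drift stack, filling uncovered
# pixels with each ion's background (minimum) level.
inject_drift <- function(stack, shifts) {
  for (ion in stack$ion_labels) {
    arr <- stack$counts[[ion]]
    fill <- min(arr)
    for (p in seq_len(stack$n_planes)) {
      arr[, , p] <- nanosip:::shift_matrix(arr[, , p], shifts[p, 1],
                                           shifts[p, 2], fill = fill)
    }
    stack$counts[[ion]] <- arr
  }
  stack
}
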