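#' Construct an ion image stack
#'
#' The pipeline's input container: per-ion, per-plane secondary-ion count
#' grids plus acquisition metadata. Counts are stored as one
#' `image_size x image_size x n_planes` array per ion; all ions share the
#' plane count and image shape. Pixel coordinates are (row, col) with row
#' increasing downward.
#'
#' @param counts Named list (ion label -> 3-D array `[row, col, plane]`).
#' @param raster_um Physical field width in micrometres.
#' @param dwell_ms Per-pixel dwell time in milliseconds.
#' @param timepoint_h Incubation time point in hours.
#' @param expectation Logical; `TRUE` marks a noise-free expectation stack
#'   (real-valued), `FALSE` an integer count stack.
#' @return A `nanosip_stack` object.
#' @export
ion_stack <- function(counts, raster_um, dwell_ms = 5, timepoint_h = 0,
                      expectation = FALSE) {
  if (!is.list(counts) || is.null(names(counts)) || anyDuplicated(names(counts)))
    abort("`counts` must be a named list with unique ion labels.")
  dims <- lapply(counts, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    abort("Each ion's counts must be a 3-D array [row, col, plane].")
  if (length(unique(lapply(dims, identity))) != 1L)
    abort("All ions must share plane count and image shape.")
  for (ion in names(counts)) {
    x <- counts[[ion]]
    if (any(x < 0)) abort(sprintf("Negative counts in ion %s.", ion))
    if (!expectation && any(abs(x - round(x)) > 1e-9))
      abort(sprintf("Non-integer counts in ion %s.", ion))
  }
  d <- dims[[1]]
  structure(
    list(counts = counts, ion_labels = names(counts),
         image_size = d[1], n_planes = d[3],
         raster_um = raster_um, dwell_ms = dwell_ms,
         timepoint_h = timepoint_h, pixel_um = raster_um / d[1],
         expectation = expectation),
    class = "nanosip_stack"
  )
}

#' @export
print.nanosip_stack <- function(x, ...) {
  cat(sprintf("Ion image stack: %s | %dx%d px, %d planes, raster %.3g um (%.4g um/px), t = %g h%s\n",
              paste(x$ion_labels, collapse = ", "),
              x$image_size, x$image_size, x$n_planes, x$raster_um,
              x$pixel_um, x$timepoint_h,
              if (x$expectation) " [expectation mode]" else ""))
  cat(sprintf("Total counts: %s\n",
              paste(sprintf("%s=%.4g", x$ion_labels,
                            vapply(x$counts, sum, 0)), collapse = " ")))
  invisible(x)
}

# Shift a matrix by (dy, dx): out[r, c] = m[r - dy, c - dx], filling
# uncovered pixels with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(fill, n_r, n_c)
  src_r <- seq_len(n_r) - dy
  src_c <- seq_len(n_c) - dx
  ok_r <- src_r >= 1L & src_r <= n_r
  ok_c <- src_c >= 1L & src_c <= n_c
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
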