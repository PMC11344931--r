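#' Estimate inter-plane translational drift
#'
#' For each plane of the reference ion, finds the integer shift
#' `(dy, dx)` within `±max_shift` that maximizes the normalized
#' (Pearson) cross-correlation with plane 1, computed on the overlap
#' region. Ties are broken by smallest shift magnitude, then row-major
#' order (dy, then dx, ascending). The reference ion defaults to 12C14N-,
#' the channel with the strongest biological contrast; one trace is used
#' for all ions since they are acquired in parallel.
#'
#' @param stack A [ion_stack()].
#' @param ref_ion Ion whose planes drive the alignment.
#' @param max_shift Maximum absolute shift searched, in pixels.
#' @return A tibble with columns `plane`, `dy`, `dx` (plane 1 is (0,0)).
#' @export
estimate_drift <- function(stack, ref_ion = "12C14N", max_shift = 10) {
  stopifnot(inherits(stack, "nanosip_stack"))
  if (!ref_ion %in% stack$ion_labels)
    abort(sprintf("Reference ion %s not in stack (%s).", ref_ion,
                  paste(stack$ion_labels, collapse = ", ")))
  if (max_shift < 0) abort("`max_shift` must be >= 0.")
  ref_arr <- stack$counts[[ref_ion]]
  ref <- ref_arr[, , 1]
  if (all(ref == 0))
    abort("Reference plane 1 is all zero: no signal to align on.")
  n <- stack$image_size
  m <- as.integer(max_shift)
  cand <- expand.grid(dx = -m:m, dy = -m:m)[, c("dy", "dx")]  # row-major in (dy, dx)

  shifts <- matrix(0L, stack$n_planes, 2)
  for (p in seq_len(stack$n_planes)[-1]) {
    plane <- ref_arr[, , p]
    ncc <- vapply(seq_len(nrow(cand)), function(i) {
      shifted_ncc(ref, plane, cand$dy[i], cand$dx[i], n)
    }, 0)
    best <- max(ncc)
    hit <- which(ncc >= best - 1e-12)
    mag <- cand$dy[hit]^2 + cand$dx[hit]^2
    hit <- hit[mag == min(mag)][1]   # candidates are already row-major
    shifts[p, ] <- c(cand$dy[hit], cand$dx[hit])
  }
  tibble(plane = seq_len(stack$n_planes), dy = shifts[, 1], dx = shifts[, 2])
}

# NCC between ref and the plane translated back by (dy, dx), on the overlap.
shifted_ncc <- function(ref, plane, dy, dx, n) {
  r <- max(1, 1 - dy):min(n, n - dy)
  c <- max(1, 1 - dx):min(n, n - dx)
  if (length(r) < 2 || length(c) < 2) return(-Inf)
  a <- as.vector(ref[r, c])
  b <- as.vector(plane[r + dy, c + dx])
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  cor(a, b)
}

#' Drift-correct and accumulate planes
#'
#' Shifts every plane of every ion back by its estimated drift and sums
#' planes into one accumulated image per ion. A validity mask records the
#' pixels covered by every shifted plane; outside it, accumulated values
#' are zero and flagged invalid, and downstream ROI statistics use only
#' valid pixels.
#'
#' @param stack A [ion_stack()].
#' @param trace A drift trace as returned by [estimate_drift()] (tibble
#'   with `plane`, `dy`, `dx`; plane 1 must be (0, 0)).
#' @return A `nanosip_accumulated` object: per-ion summed count matrices,
#'   the validity mask, and provenance (trace, metadata).
#' @export
accumulate_planes <- function(stack, trace) {
  stopifnot(inherits(stack, "nanosip_stack"))
  trace <- as_tibble(trace)
  if (!all(c("plane", "dy", "dx") %in% names(trace)))
    abort("`trace` needs columns plane, dy, dx.")
  if (nrow(trace) != stack$n_planes)
    abort(sprintf("Trace has %d planes, stack has %d.", nrow(trace), stack$n_planes))
  trace <- dplyr::arrange(trace, .data$plane)
  if (trace$dy[1] != 0 || trace$dx[1] != 0)
    abort("Plane 1 shift must be (0, 0).")
  n <- stack$image_size
  if (any(abs(trace$dy) >= n) || any(abs(trace$dx) >= n))
    abort("Shift exceeds image size.")

  valid <- matrix(TRUE, n, n)
  rows <- row(valid); cols <- col(valid)
  for (p in seq_len(stack$n_planes)) {
    valid <- valid &
      (rows + trace$dy[p] >= 1) & (rows + trace$dy[p] <= n) &
      (cols + trace$dx[p] >= 1) & (cols + trace$dx[p] <= n)
  }

  acc <- lapply(stack$counts, function(arr) {
    s <- matrix(0, n, n)
    for (p in seq_len(stack$n_planes)) {
      # corrected(r, c) = plane(r + dy, c + dx): undo the drift
      s <- s + shift_matrix(arr[, , p], -trace$dy[p], -trace$dx[p], fill = 0)
    }
    s[!valid] <- 0
    s
  })

  structure(
    list(counts = acc, valid = valid, trace = trace,
         ion_labels = stack$ion_labels, image_size = n,
         n_planes = stack$n_planes, raster_um = stack$raster_um,
         pixel_um = stack$pixel_um, timepoint_h = stack$timepoint_h,
         expectation = stack$expectation),
    class = "nanosip_accumulated"
  )
}

#' @export
print.nanosip_accumulated <- function(x, ...) {
  cat(sprintf("Accumulated NanoSIMS image: %s | %dx%d px, %d planes summed, %d%% valid, t = %g h\n",
              paste(x$ion_labels, collapse = ", "),
              x$image_size, x$image_size, x$n_planes,
              round(100 * mean(x$valid)), x$timepoint_h))
  invisible(x)
}
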