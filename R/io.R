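#' Write an ion image stack to disk
#'
#' Native on-disk format: one multi-page TIFF per ion (pages = planes;
#' 16-bit unsigned, or 32-bit float when any count exceeds 65535) plus a
#' `sidecar.json` carrying ion order, geometry and acquisition metadata.
#' The proprietary instrument format is deliberately not parsed.
#'
#' @param stack A [ion_stack()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nanosip_stack"))
  if (stack$expectation)
    abort("Expectation-mode stacks are in-memory test objects; only count stacks are serialized.")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ion in stack$ion_labels) {
    arr <- stack$counts[[ion]]
    pages <- lapply(seq_len(stack$n_planes), function(p) arr[, , p])
    f <- file.path(path, paste0("ion_", ion, ".tif"))
    bits <- if (max(arr) <= 65535) 16L else 32L
    scale <- 2^bits - 1
    if (max(arr) > scale)
      abort(sprintf("Counts in ion %s exceed the 32-bit limit.", ion))
    tiff::writeTIFF(lapply(pages, function(m) m / scale), f,
                    bits.per.sample = bits)
  }
  sidecar <- list(
    ions = stack$ion_labels,
    image_size = stack$image_size, n_planes = stack$n_planes,
    raster_um = stack$raster_um, dwell_ms = stack$dwell_ms,
    timepoint_h = stack$timepoint_h,
    total_counts = lapply(stack$counts, sum)
  )
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ion image stack from disk
#'
#' Inverse of [write_stack()]: round-trips losslessly. Malformed input
#' (missing sidecar, missing/extra ion files, shape mismatches across
#' ions, negative or non-integer pixel values) is rejected, never
#' silently coerced.
#'
#' @param path Directory written by [write_stack()].
#' @return A [ion_stack()].
#' @export
read_stack <- function(path) {
  sc_path <- file.path(path, "sidecar.json")
  if (!file.exists(sc_path)) abort(sprintf("No sidecar.json in %s.", path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  ions <- sc$ions
  files <- file.path(path, paste0("ion_", ions, ".tif"))
  missing <- ions[!file.exists(files)]
  if (length(missing) > 0)
    abort(sprintf("Sidecar lists ion(s) with no image file: %s.",
                  paste(missing, collapse = ", ")))
  extra <- setdiff(list.files(path, pattern = "^ion_.*\\.tif$"),
                   basename(files))
  if (length(extra) > 0)
    abort(sprintf("Ion file(s) not listed in sidecar: %s.",
                  paste(extra, collapse = ", ")))
  counts <- lapply(seq_along(ions), function(i) {
    pages <- tiff::readTIFF(files[i], all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample") %||% 16L
      m <- if (length(dim(p)) == 3) p[, , 1] else p
      m <- m * (2^bits - 1)   # undo TIFF normalization back to raw counts
      if (any(m < 0)) abort(sprintf("Negative pixel values in ion %s.", ions[i]))
      if (any(abs(m - round(m)) > 1e-3))
        abort(sprintf("Non-integer pixel values in ion %s.", ions[i]))
      round(m)
    })
    array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  })
  names(counts) <- ions
  shapes <- unique(lapply(counts, dim))
  if (length(shapes) != 1)
    abort("Ion images disagree in shape or plane count.")
  ion_stack(counts, raster_um = sc$raster_um, dwell_ms = sc$dwell_ms,
            timepoint_h = sc$timepoint_h)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param label_mask Integer matrix, 0 = background, k = cell k.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(label_mask, path) {
  if (max(label_mask) > 65535) abort("More than 65535 labels.")
  tiff::writeTIFF(label_mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read manual ROI masks from a labeled image
#'
#' Reads a 16-bit labeled image (0 = background, k = cell k) matching the
#' accumulated image's shape and returns one ROI per nonzero label with
#' `source = "manual"`. An all-zero label image yields an empty tibble
#' (not an error).
#'
#' @param path Labeled TIFF file.
#' @param acc The `nanosip_accumulated` image the masks belong to.
#' @return ROI tibble as from [segment_cells()], `source = "manual"`.
#' @export
read_roi_masks <- function(path, acc) {
  stopifnot(inherits(acc, "nanosip_accumulated"))
  lbl <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(lbl)) == 3) lbl <- lbl[, , 1]
  if (!identical(dim(lbl), dim(acc$valid)))
    abort(sprintf("Label image is %dx%d but the accumulated image is %dx%d.",
                  nrow(lbl), ncol(lbl), nrow(acc$valid), ncol(acc$valid)))
  ids <- sort(setdiff(unique(as.vector(lbl)), 0))
  tibble(
    cell_id = as.integer(ids),
    area_px = vapply(ids, function(k) sum(lbl == k), 0L),
    source = rep("manual", length(ids)),
    mask = lapply(ids, function(k) lbl == k)
  )
}

measurement_columns <- function() {
  c("cell_id", "timepoint_h", paste0("n_", ION_LABELS),
    "R13", "R15", "F13", "F15", "APE13", "APE15",
    "length_um", "width_um", "area_px")
}

#' Write per-cell measurements to CSV
#'
#' Fixed, documented column order: `cell_id`, `timepoint_h`, per-ion count
#' sums (`n_12C` ... `n_32S`), `R13`, `R15`, `F13`, `F15`, `APE13`,
#' `APE15`, `length_um`, `width_um`, `area_px`. Comma-separated, UTF-8,
#' '.' decimal; values round-trip through [read_measurements()] at full
#' double precision.
#'
#' @param cells Measurement tibble from [measure_cells()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(cells, path) {
  cells <- as_tibble(cells)
  missing <- setdiff(measurement_columns(), names(cells))
  if (length(missing) > 0)
    abort(sprintf("Measurement table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  if (anyDuplicated(cells[c("timepoint_h", "cell_id")]))
    abort("Duplicate (timepoint_h, cell_id) pairs.")
  readr::write_csv(cells[measurement_columns()], path)
  invisible(path)
}

#' Read a per-cell measurement CSV
#'
#' @param path CSV written by [write_measurements()].
#' @return Measurement tibble.
#' @export
read_measurements <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(measurement_columns(), names(out))
  if (length(missing) > 0)
    abort(sprintf("Measurement CSV lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  out
}
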