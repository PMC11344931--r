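#' Segment cells on an accumulated image
#'
#' Automatic stand-in for manual ROI outlining: Otsu threshold on the
#' chosen ion (computed from valid pixels only), 8-connected components,
#' per-object hole filling, and an area filter. ROIs are labeled in
#' descending area order with `source = "auto"`.
#'
#' @param acc A `nanosip_accumulated` image.
#' @param ion Ion used for thresholding (default 12C14N-, the
#'   highest-contrast biological channel).
#' @param min_area_px Components smaller than this are discarded.
#' @param min_contrast Minimum foreground/background mean-intensity ratio
#'   for the threshold to count as a real separation; below it the scene
#'   is treated as cell-free (Otsu always splits even pure counting
#'   noise, so a pure-background image would otherwise shatter into
#'   spurious ROIs).
#' @return A tibble with columns `cell_id`, `area_px`, `source`, and a
#'   `mask` list-column of logical matrices. Empty (zero rows) when the
#'   image is constant or lacks contrast, with a warning.
#' @export
segment_cells <- function(acc, ion = "12C14N", min_area_px = 20,
                          min_contrast = 2) {
  stopifnot(inherits(acc, "nanosip_accumulated"))
  if (!ion %in% acc$ion_labels)
    abort(sprintf("Ion %s not present.", ion))
  x <- acc$counts[[ion]]
  vals <- x[acc$valid]
  empty <- tibble(cell_id = integer(), area_px = integer(),
                  source = character(), mask = list())
  if (length(vals) == 0 || sd(vals) == 0) {
    warn("Constant image within the validity mask: no threshold separates foreground; returning no ROIs.")
    return(empty)
  }
  hi <- max(vals)
  thr <- EBImage::otsu(EBImage::Image(matrix(vals / hi, ncol = 1)),
                       range = c(0, 1), levels = 256L) * hi
  fg <- x > thr & acc$valid
  if (!any(fg)) {
    warn("Otsu threshold left no foreground pixels; returning no ROIs.")
    return(empty)
  }
  bg_mean <- mean(x[acc$valid & !fg])
  if (bg_mean > 0 && mean(x[fg]) / bg_mean < min_contrast) {
    warn(sprintf("Foreground/background contrast below %.2g: treating the scene as cell-free.",
                 min_contrast))
    return(empty)
  }
  lbl <- label_components8(fg)
  lbl <- EBImage::imageData(EBImage::fillHull(lbl))
  sizes <- tabulate(lbl)
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(empty)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  tibble(
    cell_id = seq_along(keep),
    area_px = as.integer(sizes[keep]),
    source = "auto",
    mask = lapply(keep, function(k) lbl == k)
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards via graph components.
label_components8 <- function(fg) {
  lbl <- EBImage::imageData(EBImage::bwlabel(fg))
  k <- max(lbl)
  if (k <= 1L) return(lbl)
  n_r <- nrow(lbl); n_c <- ncol(lbl)
  pairs <- rbind(
    diag_pairs(lbl[-n_r, -n_c], lbl[-1, -1]),     # down-right neighbour
    diag_pairs(lbl[-1, -n_c], lbl[-n_r, -1])      # up-right neighbour
  )
  if (nrow(pairs) == 0L) return(lbl)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(pairs)))
  remap <- igraph::components(g)$membership
  # renumber components consecutively
  remap <- as.integer(factor(remap, levels = unique(remap)))
  out <- lbl
  out[lbl > 0] <- remap[lbl[lbl > 0]]
  out
}

diag_pairs <- function(a, b) {
  sel <- a > 0 & b > 0 & a != b
  cbind(a[sel], b[sel])
}
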