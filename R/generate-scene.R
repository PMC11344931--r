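#' Generate a synthetic NanoSIMS scene with ground truth
#'
#' Places non-overlapping rod cells (rectangles with semicircular caps) in
#' the field, assigns each cell 13C and 15N atom fractions drawn from the
#' configured quadratic-median / growing-spread model, builds per-ion
#' expectation fields (with a 1-px 16O-enriched magnetosome-chain stripe
#' along each rod's axis and 32S proportional to total CN), applies a rigid
#' integer translation per plane (plane 1 never drifts), and draws Poisson
#' counts per pixel. Identical config, time point and replicate give
#' bit-identical output.
#'
#' @param config A [scene_config()].
#' @param timepoint_h Incubation time in hours; drives the enrichment model.
#' @param noise `TRUE` for Poisson draws; `FALSE` returns the (real-valued)
#'   expectation fields themselves, for exact geometric tests.
#' @param replicate Replicate index; mixed into the child seed so repeated
#'   scenes at one time point are independent yet reproducible.
#' @return A list with `stack` (a [ion_stack()]) and `truth`, where `truth`
#'   holds `label_mask` (0 = background, k = cell k, in the plane-1 frame),
#'   `shifts` (tibble plane/dy/dx), and `cells` (tibble of per-cell true
#'   atom fractions and geometry).
#' @export
generate_scene <- function(config, timepoint_h = 0, noise = TRUE,
                           replicate = 1L) {
  stopifnot(inherits(config, "nanosip_scene_config"))
  if (timepoint_h < 0) abort("`timepoint_h` must be >= 0.")
  seed <- child_seed(config$seed, timepoint_h, replicate)
  withr::with_seed(seed, generate_scene_impl(config, timepoint_h, noise))
}

generate_scene_impl <- function(config, timepoint_h, noise) {
  n <- config$image_size
  px <- config$pixel_um

  geom <- place_rods(config)
  label_mask <- geom$label_mask
  stripe_mask <- geom$stripe_mask

  f13 <- enrichment_trajectory(timepoint_h, config$enrich_median_coeffs$F13,
                               spread_at(config$enrich_spread$F13, timepoint_h),
                               config$n_cells)
  f15 <- enrichment_trajectory(timepoint_h, config$enrich_median_coeffs$F15,
                               spread_at(config$enrich_spread$F15, timepoint_h),
                               config$n_cells)

  br <- config$base_rate
  carbon_total <- unname(br["12C"] + br["13C"])
  cn_total <- unname(br["12C14N"] + br["12C15N"])
  f13_bg <- unname(br["13C"] / carbon_total)
  f15_bg <- unname(br["12C15N"] / cn_total)
  bg <- c("12C"    = config$bg_frac * carbon_total * (1 - f13_bg),
          "13C"    = config$bg_frac * carbon_total * f13_bg,
          "12C14N" = config$bg_frac * cn_total * (1 - f15_bg),
          "12C15N" = config$bg_frac * cn_total * f15_bg,
          "16O"    = config$bg_frac * unname(br["16O"]),
          "32S"    = config$s32_factor * config$bg_frac * cn_total)

  fields <- lapply(bg, function(b) matrix(b, n, n))
  for (k in seq_len(config$n_cells)) {
    idx <- label_mask == k
    fields$`12C`[idx]    <- carbon_total * (1 - f13[k])
    fields$`13C`[idx]    <- carbon_total * f13[k]
    fields$`12C14N`[idx] <- cn_total * (1 - f15[k])
    fields$`12C15N`[idx] <- cn_total * f15[k]
    fields$`16O`[idx]    <- br["16O"]
    fields$`32S`[idx]    <- config$s32_factor * cn_total
  }
  fields$`16O`[stripe_mask] <- fields$`16O`[stripe_mask] * config$chain_o16_boost

  m <- config$drift_max_px
  shifts <- matrix(0L, config$n_planes, 2)
  if (config$n_planes > 1L && m > 0L) {
    shifts[-1L, ] <- cbind(sample(-m:m, config$n_planes - 1L, replace = TRUE),
                           sample(-m:m, config$n_planes - 1L, replace = TRUE))
  }

  counts <- lapply(ION_LABELS, function(ion) {
    arr <- array(0, dim = c(n, n, config$n_planes))
    for (p in seq_len(config$n_planes)) {
      expt <- shift_matrix(fields[[ion]], shifts[p, 1], shifts[p, 2],
                           fill = bg[[ion]])
      arr[, , p] <- if (noise) rpois(n * n, expt) else expt
    }
    arr
  })
  names(counts) <- ION_LABELS

  stack <- ion_stack(counts, raster_um = config$raster_um,
                     dwell_ms = config$dwell_ms, timepoint_h = timepoint_h,
                     expectation = !noise)
  truth <- list(
    label_mask = label_mask,
    shifts = tibble(plane = seq_len(config$n_planes),
                    dy = shifts[, 1], dx = shifts[, 2]),
    cells = tibble(cell_id = seq_len(config$n_cells),
                   F13 = f13, F15 = f15,
                   length_um = geom$cells$length_um,
                   width_um = geom$cells$width_um,
                   theta = geom$cells$theta,
                   center_row = geom$cells$center_row,
                   center_col = geom$cells$center_col)
  )
  list(stack = stack, truth = truth)
}

# Sample non-overlapping rod geometries and rasterize label + chain-stripe
# masks. Rods are stadium shapes: the set of pixels within width/2 of the
# axial segment.
place_rods <- function(config, max_retries = 200L) {
  n <- config$image_size
  px <- config$pixel_um
  label_mask <- matrix(0L, n, n)
  stripe_mask <- matrix(FALSE, n, n)
  cells <- tibble(length_um = numeric(), width_um = numeric(),
                  theta = numeric(), center_row = numeric(),
                  center_col = numeric())
  if (config$n_cells == 0L)
    return(list(label_mask = label_mask, stripe_mask = stripe_mask,
                cells = cells))

  segs <- matrix(NA_real_, config$n_cells, 5)  # r1, c1, r2, c2, half_width_px
  for (k in seq_len(config$n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      L <- runif(1, config$cell_length_um[1], config$cell_length_um[2])
      W <- runif(1, config$cell_width_um[1], config$cell_width_um[2])
      W <- min(W, L)
      L_px <- L / px; W_px <- W / px
      a <- max((L_px - W_px) / 2, 0)   # axial half-segment
      theta <- runif(1, 0, pi)
      margin <- L_px / 2 + 2
      if (2 * margin >= n)
        abort(sprintf("Cell of length %.3g um does not fit a %d-px field at %.3g um/px (density limit).",
                      L, n, px))
      r0 <- runif(1, margin, n - margin)
      c0 <- runif(1, margin, n - margin)
      seg <- c(r0 - a * sin(theta), c0 - a * cos(theta),
               r0 + a * sin(theta), c0 + a * cos(theta), W_px / 2)
      ok <- TRUE
      for (j in seq_len(k - 1L)) {
        d <- segment_segment_distance(seg[1:4], segs[j, 1:4])
        if (d <= seg[5] + segs[j, 5] + 1) { ok <- FALSE; break }
      }
      if (ok) {
        segs[k, ] <- seg
        cells <- dplyr::bind_rows(cells, tibble(
          length_um = L, width_um = W, theta = theta,
          center_row = r0, center_col = c0))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(sprintf("Could not place cell %d of %d without overlap after %d retries: field too dense for the configured cell sizes (density limit).",
                    k, config$n_cells, max_retries))
  }

  for (k in seq_len(config$n_cells)) {
    s <- segs[k, ]
    half_w <- s[5]
    bb_r <- max(1L, floor(min(s[1], s[3]) - half_w - 1)):min(n, ceiling(max(s[1], s[3]) + half_w + 1))
    bb_c <- max(1L, floor(min(s[2], s[4]) - half_w - 1)):min(n, ceiling(max(s[2], s[4]) + half_w + 1))
    rr <- rep(bb_r, times = length(bb_c))
    cc <- rep(bb_c, each = length(bb_r))
    d <- point_segment_distance(rr, cc, s[1], s[2], s[3], s[4])
    inside <- d <= half_w
    label_mask[cbind(rr[inside], cc[inside])] <- k
    on_axis <- d <= 0.5 & inside
    stripe_mask[cbind(rr[on_axis], cc[on_axis])] <- TRUE
  }
  list(label_mask = label_mask, stripe_mask = stripe_mask, cells = cells)
}

# Distance from points (pr, pc) to segment (r1,c1)-(r2,c2); vectorized over
# points.
point_segment_distance <- function(pr, pc, r1, c1, r2, c2) {
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr^2 + vc^2
  if (len2 < 1e-12) return(sqrt((pr - r1)^2 + (pc - c1)^2))
  t <- ((pr - r1) * vr + (pc - c1) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pr - (r1 + t * vr))^2 + (pc - (c1 + t * vc))^2)
}

# Minimum distance between two segments, via endpoint-to-segment distances
# (sufficient for non-intersecting segments; intersection gives ~0 anyway
# through the sampled interior points).
segment_segment_distance <- function(s1, s2) {
  if (segments_intersect(s1, s2)) return(0)
  min(point_segment_distance(s1[1], s1[2], s2[1], s2[2], s2[3], s2[4]),
      point_segment_distance(s1[3], s1[4], s2[1], s2[2], s2[3], s2[4]),
      point_segment_distance(s2[1], s2[2], s1[1], s1[2], s1[3], s1[4]),
      point_segment_distance(s2[3], s2[4], s1[1], s1[2], s1[3], s1[4]))
}

segments_intersect <- function(s1, s2) {
  o <- function(ar, ac, br, bc, cr, cc)
    sign((bc - ac) * (cr - ar) - (br - ar) * (cc - ac))
  o1 <- o(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
  o2 <- o(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
  o3 <- o(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
  o4 <- o(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
  (o1 != o2) && (o3 != o4)
}
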