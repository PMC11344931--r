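make_acc <- function(counts, pixel_um = 0.1, valid = NULL) {
  n <- nrow(counts[[1]])
  structure(
    list(counts = counts, valid = valid %||% matrix(TRUE, n, ncol(counts[[1]])),
         trace = tibble::tibble(plane = 1L, dy = 0L, dx = 0L),
         ion_labels = names(counts), image_size = n, n_planes = 1L,
         raster_um = pixel_um * n, pixel_um = pixel_um, timepoint_h = 0,
         expectation = FALSE),
    class = "nanosip_accumulated")
}

`%||%` <- rlang::`%||%`

test_that("ratios are ratio-of-sums and map to fractions and APE correctly", {
  n <- 16
  mk <- function(v) matrix(v, n, n)
  counts <- list(`12C` = mk(10000 / 256), `13C` = mk(112 / 256),
                 `12C14N` = mk(100), `12C15N` = mk(0.37),
                 `16O` = mk(1), `32S` = mk(1))
  acc <- make_acc(counts)
  mask <- matrix(TRUE, n, n)
  m <- measure_cell(acc, mask)
  expect_equal(m$R13, 0.0112, tolerance = 1e-12)
  expect_equal(m$R15, 0.0037, tolerance = 1e-12)
  expect_equal(m$F13, 0.0112 / 1.0112, tolerance = 1e-12)
  # at exactly natural abundance the enrichment is zero
  expect_equal(m$APE13, 0, tolerance = 1e-12)
  expect_equal(m$APE15, 0, tolerance = 1e-12)
})

test_that("zero rare-isotope signal gives R = 0 and the negative-baseline APE", {
  n <- 8
  counts <- list(`12C` = matrix(100, n, n), `13C` = matrix(0, n, n),
                 `12C14N` = matrix(100, n, n), `12C15N` = matrix(0, n, n),
                 `16O` = matrix(1, n, n), `32S` = matrix(1, n, n))
  m <- measure_cell(make_acc(counts), matrix(TRUE, n, n))
  nat <- natural_abundance()
  expect_equal(m$R13, 0)
  expect_equal(m$F13, 0)
  expect_equal(m$APE13, -100 * nat$R13 / (1 + nat$R13), tolerance = 1e-12)
})

test_that("zero denominator sums raise an error naming the ion", {
  n <- 8
  counts <- list(`12C` = matrix(0, n, n), `13C` = matrix(1, n, n),
                 `12C14N` = matrix(100, n, n), `12C15N` = matrix(1, n, n),
                 `16O` = matrix(1, n, n), `32S` = matrix(1, n, n))
  expect_error(measure_cell(make_acc(counts), matrix(TRUE, n, n)), "12C")
})

test_that("ROI pixels outside the validity mask are dropped with a warning", {
  n <- 8
  counts <- list(`12C` = matrix(100, n, n), `13C` = matrix(1, n, n),
                 `12C14N` = matrix(100, n, n), `12C15N` = matrix(1, n, n),
                 `16O` = matrix(1, n, n), `32S` = matrix(1, n, n))
  valid <- matrix(TRUE, n, n); valid[, 1] <- FALSE
  mask <- matrix(TRUE, n, n)
  expect_warning(m <- measure_cell(make_acc(counts, valid = valid), mask),
                 "dropped")
  expect_equal(m$area_px, n * (n - 1))
})

test_that("measured F13 recovers the generator truth within Poisson error", {
  cfg <- small_config(n_cells = 1, drift_max_px = 0, seed = 41,
                      enrich_median_coeffs = list(F13 = c(0, 0, 0.5),
                                                  F15 = c(0, 0, 0.1)))
  sc <- generate_scene(cfg)
  acc <- accumulate_planes(sc$stack, sc$truth$shifts)
  mask <- sc$truth$label_mask == 1
  m <- measure_cell(acc, mask)
  n13 <- m$n_13C; n12 <- m$n_12C
  se_R <- m$R13 * sqrt(1 / n13 + 1 / n12)
  se_F <- se_R / (1 + m$R13)^2
  expect_lt(abs(m$F13 - 0.5), 3 * se_F)
})

test_that("ratio estimator bias is below 1% at denominator sums >= 1e4", {
  set.seed(77)
  lam12 <- 1e4; R_true <- 0.0112
  r <- vapply(seq_len(1000), function(i) {
    rpois(1, lam12 * R_true) / rpois(1, lam12)
  }, 0)
  expect_lt(abs(mean(r) - R_true) / R_true, 0.01)
})

test_that("measurement is invariant to translating scene and ROI together", {
  n <- 16
  base <- matrix(1, n, n); base[5:9, 4:12] <- 50
  counts <- list(`12C` = base, `13C` = base * 0.0112,
                 `12C14N` = base, `12C15N` = base * 0.0037,
                 `16O` = base, `32S` = base)
  mask <- base > 1
  m1 <- measure_cell(make_acc(counts), mask)
  sh <- lapply(counts, nanosip:::shift_matrix, dy = 3, dx = 2, fill = 1)
  m2 <- measure_cell(make_acc(sh), nanosip:::shift_matrix(mask, 3, 2, FALSE) > 0)
  expect_equal(m1$R13, m2$R13)
  expect_equal(m1$length_um, m2$length_um)
  expect_equal(m1$width_um, m2$width_um)
})

test_that("rod morphometrics match the definition on axis-aligned rectangles", {
  mask <- matrix(FALSE, 80, 80)
  mask[11:60, 21:30] <- TRUE   # 50 x 10 px
  m <- rod_morphometrics(mask, 0.1)
  expect_equal(m$length_um, 5.0, tolerance = 1e-12)
  expect_equal(m$width_um, 1.0, tolerance = 1e-12)
  # single pixel object has size one pixel
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_equal(rod_morphometrics(px, 0.1), list(length_um = 0.1, width_um = 0.1))
})

test_that("rod morphometrics are rotation-invariant to within 1.5 px", {
  # rasterize a 50 x 10 px rectangle rotated by 30 degrees
  theta <- 30 * pi / 180
  n <- 90
  ctr <- (n + 1) / 2
  rr <- rep(1:n, n); cc <- rep(1:n, each = n)
  u <- (rr - ctr) * cos(theta) + (cc - ctr) * sin(theta)
  v <- -(rr - ctr) * sin(theta) + (cc - ctr) * cos(theta)
  mask <- matrix(abs(u) <= 25 & abs(v) <= 5, n, n)
  m <- rod_morphometrics(mask, 0.1)
  expect_lt(abs(m$length_um - 5.0), 0.15)
  expect_lt(abs(m$width_um - 1.0), 0.15)
  expect_gte(m$length_um, m$width_um)
})

test_that("crystal summaries handle degenerate and exactly linear populations", {
  cr <- tibble::tibble(length_nm = rep(100, 6), width_nm = rep(43, 6))
  cs <- crystal_summary(cr)
  expect_equal(cs$mean_length_nm, 100)
  expect_equal(cs$sd_length_nm, 0)
  expect_equal(cs$mean_shape_factor, 0.43)
  h <- cs$histogram[[1]]
  expect_equal(h$count[h$bin_lower == 100], 6)
  expect_equal(sum(h$count), 6)

  set.seed(1)
  len <- runif(50, 80, 140)
  cs2 <- crystal_summary(tibble::tibble(length_nm = len, width_nm = 0.5 * len))
  expect_equal(cs2$slope, 0.5, tolerance = 1e-9)
  expect_equal(cs2$intercept, 0, tolerance = 1e-7)
  expect_equal(cs2$r, 1, tolerance = 1e-9)

  expect_error(crystal_summary(tibble::tibble(length_nm = numeric(),
                                              width_nm = numeric())), "Empty")
})

test_that("mixture moments: equal 95/115 components average to 105", {
  cfg <- crystal_mixture_config(1e4, weights = c(0.5, 0.5),
                                mean_length_nm = c(95, 115),
                                sd_length_nm = c(5, 5), seed = 8)
  cs <- crystal_summary(generate_crystal_population(cfg))
  expect_lt(abs(cs$mean_length_nm - 105), 1)
})
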