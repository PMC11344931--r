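#' Configure a magnetosome-crystal mixture population
#'
#' Crystal lengths are drawn from a Gaussian mixture (bimodal length
#' distributions are typical of bullet-shaped magnetosome populations);
#' each crystal's shape factor (width/length) is drawn from its
#' component's Gaussian truncated to (0, 1], and width = length x shape
#' factor, so width never exceeds length.
#'
#' @param n Number of crystals (> 0).
#' @param weights Mixture weights (must sum to 1).
#' @param mean_length_nm,sd_length_nm Per-component length moments (nm);
#'   draws are truncated to be positive.
#' @param mean_shape,sd_shape Per-component shape-factor moments.
#' @param seed Optional seed.
#' @return A `nanosip_crystal_config` list.
#' @export
crystal_mixture_config <- function(n,
                                   weights = c(0.5, 0.5),
                                   mean_length_nm = c(95, 115),
                                   sd_length_nm = c(5, 5),
                                   mean_shape = c(0.43, 0.43),
                                   sd_shape = c(0.05, 0.05),
                                   seed = NULL) {
  if (n <= 0) abort("`n` must be positive.")
  k <- length(weights)
  if (abs(sum(weights) - 1) > 1e-9) abort("`weights` must sum to 1.")
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  for (v in list(mean_length_nm, sd_length_nm, mean_shape, sd_shape))
    if (length(v) != k) abort("All component parameter vectors must share the number of components.")
  if (any(mean_length_nm <= 0)) abort("Mean lengths must be positive.")
  if (any(sd_length_nm < 0) || any(sd_shape < 0)) abort("SDs must be >= 0.")
  if (any(mean_shape <= 0) || any(mean_shape > 1))
    abort("Mean shape factors must lie in (0, 1].")
  structure(list(n = as.integer(n), weights = weights,
                 mean_length_nm = mean_length_nm, sd_length_nm = sd_length_nm,
                 mean_shape = mean_shape, sd_shape = sd_shape, seed = seed),
            class = "nanosip_crystal_config")
}

#' Draw a synthetic crystal population
#'
#' @param config A [crystal_mixture_config()].
#' @return Tibble with `component`, `length_nm`, `width_nm`,
#'   `shape_factor` (one row per crystal).
#' @export
generate_crystal_population <- function(config) {
  stopifnot(inherits(config, "nanosip_crystal_config"))
  draw <- function() {
    comp <- sample.int(length(config$weights), config$n, replace = TRUE,
                       prob = config$weights)
    len <- truncated_normal(config$n, config$mean_length_nm[comp],
                            config$sd_length_nm[comp], lower = 1e-6)
    sf <- truncated_normal(config$n, config$mean_shape[comp],
                           config$sd_shape[comp], lower = 1e-6, upper = 1)
    tibble(component = comp, length_nm = len,
           width_nm = len * sf, shape_factor = sf)
  }
  if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
}

# Normal draws truncated by rejection (resample out-of-range values).
# `mean` and `sd` are recycled to length n before use.
truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower | x > upper)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

#' Summarize a crystal population
#'
#' Length histogram on fixed 10-nm bins, length mean and SD, mean shape
#' factor, and the ordinary-least-squares regression of width on length
#' (with Pearson r), as used to characterize crystal growth anisotropy.
#'
#' @param crystals Tibble with `length_nm`, `width_nm` (and optionally
#'   `shape_factor`, otherwise computed).
#' @param bin_nm Histogram bin width, default 10 nm, bins `[0,10), [10,20), ...`.
#' @return One-row tibble: `n`, `mean_length_nm`, `sd_length_nm`,
#'   `mean_shape_factor`, `slope`, `intercept`, `r`, and a `histogram`
#'   list-column (tibble `bin_lower`, `bin_upper`, `count`).
#' @export
crystal_summary <- function(crystals, bin_nm = 10) {
  crystals <- as_tibble(crystals)
  if (nrow(crystals) == 0L) abort("Empty crystal table.")
  if (!all(c("length_nm", "width_nm") %in% names(crystals)))
    abort("`crystals` needs columns length_nm and width_nm.")
  if (any(crystals$width_nm > crystals$length_nm + 1e-9))
    abort("Crystal width must not exceed length.")
  sf <- if ("shape_factor" %in% names(crystals)) crystals$shape_factor
        else crystals$width_nm / crystals$length_nm
  len <- crystals$length_nm
  edges <- seq(0, (max(len) %/% bin_nm + 1) * bin_nm, by = bin_nm)
  counts <- tabulate(findInterval(len, edges), nbins = length(edges) - 1)
  hist_tbl <- tibble(bin_lower = edges[-length(edges)],
                     bin_upper = edges[-1], count = counts)
  if (nrow(crystals) >= 2L && sd(len) > 0) {
    fit <- stats::lm(width_nm ~ length_nm, data = crystals)
    slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
    r <- if (sd(crystals$width_nm) > 0) cor(len, crystals$width_nm) else NA_real_
  } else {
    slope <- NA_real_; intercept <- NA_real_; r <- NA_real_
  }
  tibble(n = nrow(crystals),
         mean_length_nm = mean(len),
         sd_length_nm = if (nrow(crystals) > 1) sd(len) else 0,
         mean_shape_factor = mean(sf),
         slope = slope, intercept = intercept, r = r,
         histogram = list(hist_tbl))
}
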