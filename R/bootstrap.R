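#' Subsample-median bootstrap polynomial trend fit
#'
#' The trend of a per-cell variable over incubation time is estimated by
#' a resampling scheme designed to be robust to non-uniform, outlier-prone
#' single-cell data: in each of `n_reps` repetitions, 70% of the cells at
#' each time point are randomly sampled (without replacement by default),
#' the per-time-point medians of the subsample are computed, and a
#' second-order polynomial is least-squares-fitted to the (time, median)
#' points. After all repetitions, each coefficient's empirical
#' distribution is binned (Freedman-Diaconis widths) and the modal bin
#' center is reported as the final coefficient — the "most frequent"
#' fitting parameter. The residual sum of squares (RSS) of the modal
#' polynomial is evaluated against the full-data per-time-point medians.
#'
#' With `subsample_fraction = 1` and `n_reps = 1` the procedure reduces
#' exactly to a single least-squares fit of the full-data medians.
#'
#' @param data Tibble with columns `timepoint_h` and the chosen variable.
#' @param variable Column to fit.
#' @param subsample_fraction Fraction sampled per time point per rep; the
#'   subsample size is `ceiling(fraction * n)`, so groups are never empty.
#' @param n_reps Number of repetitions.
#' @param poly_order Polynomial order (default 2).
#' @param replace Sample with replacement instead of taking a subset.
#' @param seed Optional seed; results are identical across runs at a
#'   fixed seed.
#' @param keep_reps Retain the full coefficient table (`poly_order + 1` x
#'   `n_reps`) in the result.
#' @param joint_mode Select the jointly most frequent coefficient triple
#'   (mode of the multi-dimensional histogram on the same bins) instead
#'   of per-coefficient modes.
#' @return A `nanosip_bootfit` object; see [tidy.nanosip_bootfit()],
#'   [glance.nanosip_bootfit()], [autoplot.nanosip_bootfit()].
#' @export
bootstrap_polyfit <- function(data, variable = "R13",
                              subsample_fraction = 0.7,
                              n_reps = 10000, poly_order = 2,
                              replace = FALSE, seed = NULL,
                              keep_reps = FALSE, joint_mode = FALSE) {
  data <- as_tibble(data)
  if (!variable %in% names(data))
    abort(sprintf("Column %s not found.", variable))
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    abort("`subsample_fraction` must be in (0, 1].")
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (poly_order < 0) abort("`poly_order` must be >= 0.")
  keep <- !is.na(data[[variable]]) & !is.na(data$timepoint_h)
  data <- data[keep, ]
  groups <- split(data[[variable]], data$timepoint_h)
  times <- as.numeric(names(groups))
  ord <- order(times); times <- times[ord]; groups <- groups[ord]
  n_t <- length(times)
  if (n_t < poly_order + 1)
    abort(sprintf("Need at least %d time points for a degree-%d fit; got %d.",
                  poly_order + 1, poly_order, n_t))
  if (any(lengths(groups) < 1)) abort("Every time point needs >= 1 value.")

  # design matrix columns t^order, ..., t, 1 so coefficients read (c2, c1, c0)
  X <- outer(times, seq(poly_order, 0), `^`)
  P <- solve(crossprod(X), t(X))          # (order+1) x n_t projector

  meds <- matrix(0, n_t, n_reps)
  run <- function() {
    for (g in seq_len(n_t)) {
      v <- groups[[g]]
      n_g <- length(v)
      k <- ceiling(subsample_fraction * n_g)
      if (!replace && k == n_g) {
        meds[g, ] <<- median(v)
      } else {
        draws <- vapply(seq_len(n_reps),
                        function(i) median(v[sample.int(n_g, k, replace = replace)]),
                        0)
        meds[g, ] <<- draws
      }
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())

  coef_mat <- P %*% meds                   # (order+1) x n_reps
  terms <- paste0("c", seq(poly_order, 0))
  rownames(coef_mat) <- terms

  hists <- lapply(terms, function(tm) coef_histogram(coef_mat[tm, ]))
  names(hists) <- terms
  modal <- if (joint_mode) joint_modal(coef_mat, hists)
           else vapply(hists, function(h) h$mode, 0)
  names(modal) <- terms

  full_meds <- vapply(groups, median, 0)
  rss <- sum((full_meds - as.vector(X %*% modal))^2)

  structure(
    list(coefficients = modal,
         histograms = lapply(hists, function(h) h$table),
         rss = rss, variable = variable,
         times = times, medians = unname(full_meds),
         group_n = unname(lengths(groups)),
         n_reps = n_reps, subsample_fraction = subsample_fraction,
         poly_order = poly_order, replace = replace,
         joint_mode = joint_mode, seed = seed,
         reps = if (keep_reps) coef_mat else NULL),
    class = "nanosip_bootfit"
  )
}

# Freedman-Diaconis histogram of one coefficient's replicate values, with
# the modal bin center. Degenerate (all equal) distributions report the
# common value itself as the mode, in a single bin.
coef_histogram <- function(x) {
  rng <- diff(range(x))
  if (rng < 1e-12 * max(1, abs(mean(x)))) {
    tbl <- tibble(bin_lower = min(x) - .Machine$double.eps,
                  bin_upper = max(x) + .Machine$double.eps,
                  bin_mid = mean(range(x)), count = length(x))
    return(list(table = tbl, mode = mean(range(x))))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  tbl <- tibble(bin_lower = h$breaks[-length(h$breaks)],
                bin_upper = h$breaks[-1],
                bin_mid = h$mids, count = h$counts)
  list(table = tbl, mode = h$mids[which.max(h$counts)])
}

# Joint mode: bin every coefficient on its own FD grid, then find the most
# frequent joint bin; report that bin's centers.
joint_modal <- function(coef_mat, hists) {
  keys <- apply(vapply(seq_len(nrow(coef_mat)), function(i) {
    h <- hists[[i]]$table
    findInterval(coef_mat[i, ], h$bin_lower, rightmost.closed = TRUE)
  }, integer(ncol(coef_mat))), 1, paste, collapse = "|")
  top <- names(sort(table(keys), decreasing = TRUE))[1]
  bins <- as.integer(strsplit(top, "|", fixed = TRUE)[[1]])
  vapply(seq_along(bins), function(i) hists[[i]]$table$bin_mid[bins[i]], 0)
}

#' @export
print.nanosip_bootfit <- function(x, ...) {
  co <- paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(sprintf("Subsample-median bootstrap polynomial fit of %s\n", x$variable))
  cat(sprintf("  %d reps, %.0f%% subsample %s replacement, order %d\n",
              x$n_reps, 100 * x$subsample_fraction,
              if (x$replace) "with" else "without", x$poly_order))
  cat(sprintf("  modal coefficients: %s\n  RSS vs full-data medians: %.6g\n",
              co, x$rss))
  invisible(x)
}

#' Tidy a bootstrap polynomial fit
#'
#' @param x A `nanosip_bootfit`.
#' @param ... Unused.
#' @return Tibble with one row per polynomial term: `term`, `estimate`
#'   (modal value), and the spread of the replicate distribution
#'   (`q2.5`, `q97.5`).
#' @method tidy nanosip_bootfit
#' @export
tidy.nanosip_bootfit <- function(x, ...) {
  qs <- lapply(x$histograms, function(h) {
    # approximate replicate quantiles from the histogram
    cum <- cumsum(h$count) / sum(h$count)
    c(lo = h$bin_mid[which(cum >= 0.025)[1]],
      hi = h$bin_mid[which(cum >= 0.975)[1]])
  })
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         q2.5 = vapply(qs, `[[`, 0, "lo"),
         q97.5 = vapply(qs, `[[`, 0, "hi"))
}

#' One-row summary of a bootstrap polynomial fit
#'
#' @param x A `nanosip_bootfit`.
#' @param ... Unused.
#' @return One-row tibble: `variable`, `rss`, `n_reps`,
#'   `subsample_fraction`, `poly_order`, `n_timepoints`.
#' @method glance nanosip_bootfit
#' @export
glance.nanosip_bootfit <- function(x, ...) {
  tibble(variable = x$variable, rss = x$rss, n_reps = x$n_reps,
         subsample_fraction = x$subsample_fraction,
         poly_order = x$poly_order, n_timepoints = length(x$times))
}

#' Evaluate the modal polynomial
#'
#' @param object A `nanosip_bootfit`.
#' @param newdata Optional tibble with `timepoint_h`; defaults to the
#'   fitted time points.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.nanosip_bootfit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else newdata$timepoint_h
  X <- outer(t, seq(object$poly_order, 0), `^`)
  as.vector(X %*% object$coefficients)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
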