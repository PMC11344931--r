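#' Run the full simulate -> process -> quantify -> stats pipeline
#'
#' For each requested time point (and replicate scenes within it):
#' generate a synthetic scene, estimate inter-plane drift, accumulate
#' planes, segment cells (or import manual ROI masks), and quantify every
#' cell; then fit the bootstrap polynomial trend and heterogeneity
#' profile per variable and run all pairwise time-point comparisons.
#' Deterministic end to end at a fixed root seed; when `outdir` is given,
#' every artifact (stacks, measurement CSV, stats JSON, resolved config)
#' is written there.
#'
#' @param config A [scene_config()]; its `seed` is the root seed.
#' @param timepoints_h Time points to simulate (default [sip_timepoints()]).
#' @param scenes_per_timepoint Replicate scenes per time point.
#' @param variables Variables passed to the statistics stage.
#' @param outdir Optional output directory.
#' @param roi_source `"auto"` for [segment_cells()]; `"truth"` uses the
#'   generator's label masks (the synthetic analogue of manual outlining).
#' @param n_reps Bootstrap repetitions for the trend fits.
#' @param write_stacks Also serialize every generated stack (off by
#'   default; they are bulky).
#' @return A list with `measurements` (tibble), `fits` (per-variable
#'   `nanosip_bootfit`), `heterogeneity`, `pairwise`, and `traces`.
#' @export
run_pipeline <- function(config,
                         timepoints_h = sip_timepoints(),
                         scenes_per_timepoint = 1L,
                         variables = c("R13", "R15"),
                         outdir = NULL,
                         roi_source = c("auto", "truth"),
                         n_reps = 1000,
                         write_stacks = FALSE) {
  stopifnot(inherits(config, "nanosip_scene_config"))
  roi_source <- match.arg(roi_source)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  traces <- list()
  measurements <- purrr::map_dfr(timepoints_h, function(tp) {
    purrr::map_dfr(seq_len(scenes_per_timepoint), function(rep) {
      scene <- generate_scene(config, timepoint_h = tp, replicate = rep)
      trace <- estimate_drift(scene$stack, max_shift = config$drift_max_px + 2)
      acc <- accumulate_planes(scene$stack, trace)
      rois <- if (roi_source == "auto") {
        segment_cells(acc)
      } else {
        truth_rois(scene$truth$label_mask)
      }
      traces[[sprintf("t%g_rep%d", tp, rep)]] <<- trace
      if (!is.null(outdir) && write_stacks)
        write_stack(scene$stack, file.path(outdir,
                                           sprintf("stack_t%g_rep%d", tp, rep)))
      m <- measure_cells(acc, rois, natural = config$natural)
      if (nrow(m) > 0) m$scene_replicate <- rep
      m
    })
  })
  # replicate-unique cell ids within a time point
  if (nrow(measurements) > 0) {
    measurements <- measurements |>
      dplyr::group_by(.data$timepoint_h) |>
      dplyr::mutate(cell_id = dplyr::row_number()) |>
      dplyr::ungroup()
  }

  fits <- NULL; het <- NULL; pairwise <- NULL
  enough_points <- length(unique(measurements$timepoint_h)) >= 3
  if (nrow(measurements) > 0 && enough_points) {
    fits <- lapply(setNames(variables, variables), function(v)
      bootstrap_polyfit(measurements, variable = v, n_reps = n_reps,
                        seed = child_seed(config$seed, 999, match(v, variables))))
    het <- lapply(setNames(variables, variables), function(v)
      heterogeneity_profile(measurements, variable = v))
    pairwise <- lapply(setNames(variables, variables), function(v)
      tryCatch(compare_timepoints(measurements, variable = v),
               error = function(e) NULL))
  }

  if (!is.null(outdir)) {
    write_measurements(measurements[order(measurements$timepoint_h,
                                          measurements$cell_id), ],
                       file.path(outdir, "measurements.csv"))
    report <- list(
      seed = config$seed,
      config = resolved_config(config),
      traces = lapply(traces, function(tr) as.list(tr)),
      fits = lapply(fits, function(f) list(
        variable = f$variable, coefficients = as.list(f$coefficients),
        rss = f$rss, n_reps = f$n_reps)),
      heterogeneity = lapply(het, function(h)
        c(list(profile = as.data.frame(h)), as.list(heterogeneity_trend(h))))
    )
    jsonlite::write_json(report, file.path(outdir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(measurements = measurements, fits = fits, heterogeneity = het,
       pairwise = pairwise, traces = traces)
}

# ROI tibble straight from a generator truth label mask.
truth_rois <- function(label_mask) {
  ids <- sort(setdiff(unique(as.vector(label_mask)), 0))
  tibble(
    cell_id = as.integer(ids),
    area_px = vapply(ids, function(k) sum(label_mask == k), 0L),
    source = rep("manual", length(ids)),
    mask = lapply(ids, function(k) label_mask == k)
  )
}

# JSON-serializable echo of the fully-resolved scene config.
resolved_config <- function(config) {
  out <- unclass(config)
  out$natural <- unclass(out$natural)
  out$enrich_spread <- lapply(out$enrich_spread, function(s)
    if (is.function(s)) "function" else s)
  out
}
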