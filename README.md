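# nanosip

Single-cell stable-isotope-probing (SIP) analysis for NanoSIMS
secondary-ion image stacks, in R.

NanoSIMS counts sputtered secondary ions per pixel, producing one image
per ion species (here 12C-, 13C-, 12C14N-, 12C15N-, 16O-, 32S-) over
repeated raster passes ("planes") that drift between acquisitions. For
cells incubated with 13C-bicarbonate and 15N-nitrate, the per-cell count
ratios

    R13 = Σ13C- / Σ12C-        R15 = Σ12C15N- / Σ12C14N-   (≙ 15N/14N)

measure isotope uptake against the natural-abundance baselines
R13 = 0.0112 and R15 = 0.0037; atom fraction F = R/(1+R) and atom
percent enrichment APE = 100·(F − F_nat) are derived per cell.

The package provides the whole computational chain:

* **Synthetic scenes with ground truth** — `scene_config()`,
  `generate_scene()`: non-overlapping rod cells, per-ion Poisson count
  fields with exact F/(1−F) isotope splits, a 16O-enriched
  magnetosome-chain stripe, per-plane integer drift, and enrichment
  whose median follows a quadratic in time with cell-to-cell spread
  growing over incubation (`study_enrichment()`).
* **Image processing** — `estimate_drift()` (exhaustive normalized
  cross-correlation over integer shifts), `accumulate_planes()`
  (drift-corrected plane summation with a validity mask),
  `segment_cells()` (Otsu + 8-connected components + hole filling).
* **Quantification** — `measure_cells()` (pooled ratio-of-sums per ROI,
  fractions, APE), `rod_morphometrics()` (moment-based length/width),
  `crystal_summary()` (10-nm length histograms, shape factors,
  width-vs-length regression).
* **Statistics** — `test_normality()` / `compare_groups()` /
  `compare_timepoints()` (Shapiro–Wilk-gated Student t vs Mann–Whitney
  U), `bootstrap_polyfit()` (the 70%-subsample median bootstrap with
  second-order polynomial fit and modal-coefficient selection),
  `heterogeneity_profile()` (IQR-vs-time dispersion trend).
* **IO and orchestration** — per-ion multi-page TIFF + JSON sidecar
  stacks, 16-bit label masks, fixed-layout measurement CSVs,
  `run_pipeline()` for simulate → process → quantify → stats with
  end-to-end seed determinism, plus `plot_isotope_scatter()`,
  `autoplot()`, `tidy()`/`glance()` for results.

## Worked example

```r
library(nanosip)

cfg <- scene_config(n_cells = 5, seed = 42)   # unlabeled, 256 px, 6 planes
sc  <- generate_scene(cfg, timepoint_h = 0)
tr  <- estimate_drift(sc$stack, max_shift = 5)
acc <- accumulate_planes(sc$stack, tr)
m   <- measure_cells(acc, segment_cells(acc))
dplyr::select(m, cell_id, R13, R15, F13, length_um, width_um)
#> # A tibble: 5 × 6
#>   cell_id    R13     R15    F13 length_um width_um
#>     <int>  <dbl>   <dbl>  <dbl>     <dbl>    <dbl>
#> 1       1 0.0112 0.00367 0.0110      5.92     1.19
#> 2       2 0.0114 0.00369 0.0112      5.34     1.20
#> 3       3 0.0111 0.00363 0.0110      4.52     1.25
#> 4       4 0.0110 0.00369 0.0109      4.60     1.06
#> 5       5 0.0111 0.00375 0.0109      4.10     1.11
```

The recovered drift trace equals the injected truth, and every unlabeled
cell sits at the natural-abundance baselines (R13 ≈ 0.0112,
R15 ≈ 0.0037) within Poisson counting error; lengths and widths match
the configured 4–6.5 um × 0.8–1.2 um rods.

A labeled time course, fitted and plotted:

```r
en  <- study_enrichment()
cfg <- scene_config(n_cells = 5, enrich_median_coeffs = en$coeffs,
                    enrich_spread = en$spread, seed = 1)
res <- run_pipeline(cfg, timepoints_h = sip_timepoints(),
                    scenes_per_timepoint = 2, n_reps = 10000)
res$fits$R13
#> Subsample-median bootstrap polynomial fit of R13
#>   10000 reps, 70% subsample without replacement, order 2
#>   modal coefficients: c2 = -3.5e-05, c1 = 0.002075, c0 = 0.011575
#>   RSS vs full-data medians: 2.08803e-05
autoplot(res$fits$R13, data = res$measurements)
heterogeneity_trend(res$heterogeneity$R13)
#> # A tibble: 1 × 3
#>   variable spearman_rho flag
#>   <chr>           <dbl> <chr>
#> 1 R13             0.905 ""
```

The modal coefficients recover the generating trajectory
(c2 = -4.5e-05, c1 = 2.1e-03, c0 = 0.0111) to within the resampling
noise of 10 cells per time point, and the heterogeneity trend reflects
the generator's linearly growing cell-to-cell spread.

See `vignettes/nanosip-methods.Rmd` for the model, parameter meanings,
and numerical choices.

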