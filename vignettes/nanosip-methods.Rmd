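---
title: "Methods: single-cell isotope-probing analysis of NanoSIMS image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell isotope-probing analysis of NanoSIMS image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosip)
```

# The measurement problem

NanoSIMS rasters a Cs+ primary beam over a field of cells and counts
sputtered secondary ions per pixel, one image per ion species, with six
ions (12C-, 13C-, 12C14N-, 12C15N-, 16O-, 32S-) acquired in parallel.
Repeated passes ("planes") over the same field accumulate counts, but the
stage and beam drift between passes, so planes must be registered before
summation. In a stable-isotope-probing (SIP) experiment, cells incubated
with 13C-bicarbonate and 15N-nitrate incorporate the heavy isotopes into
biomass; the per-cell count ratios

$$R_{13} = \frac{\sum \mathrm{^{13}C^-}}{\sum \mathrm{^{12}C^-}}, \qquad
  R_{15} = \frac{\sum \mathrm{^{12}C^{15}N^-}}{\sum \mathrm{^{12}C^{14}N^-}}$$

measure uptake relative to the natural-abundance baselines
$R_{13}^{nat} = 0.0112$ and $R_{15}^{nat} = 0.0037$. Atom fractions are
$F = R/(1+R)$ and atom-percent enrichment is
$\mathrm{APE} = 100\,(F - F^{nat})$.

This package implements the full computational chain — drift correction,
plane accumulation, segmentation, per-cell quantification, morphometrics,
and the statistical layer — together with a synthetic scene generator
that supplies ground truth for every stage.

# The synthetic-scene model

`scene_config()` + `generate_scene()` emulate one acquisition:

* **Geometry.** Rod-shaped cells are stadium shapes (a rectangle with
  semicircular caps): length and width are drawn uniformly from
  configurable ranges (defaults 4–6.5 um by 0.8–1.2 um, the scale of
  large rod-shaped magnetotactic bacteria), orientation is uniform, and
  placement rejects overlaps; an unplaceable configuration errors with a
  density-limit message rather than silently overlapping. The default
  field is 256 x 256 px at a 20 um raster (0.078 um/px) with six planes
  and a 5 ms/px dwell.
* **Counting.** Every pixel of every plane is an independent Poisson
  draw from an expectation field. In-cell isotope-channel expectations
  are the channel total (e.g. 12C- + 13C-) split by the cell's atom
  fraction, so the expectation-field count ratio is exactly $F/(1-F)$.
  Background is a configurable fraction (default 1%) of the in-cell
  rate, per ion, which keeps the background itself at natural abundance.
  The default in-cell 12C- rate (200 counts/px/plane) is chosen for
  statistical power: a ~800-px cell then collects ~10^6 12C- counts over
  six planes, putting the per-cell ratio noise near 1%. Absolute count
  magnitudes on real instruments vary with beam current and dwell and
  are not calibrated here.
* **Structure.** A 1-px stripe along each rod's major axis multiplies
  the 16O- expectation (default x3), standing in for the magnetosome
  chain (magnetite retains more 16O- than cytoplasm); 32S- is
  proportional to the total CN expectation (default 0.3), encoding its
  observed colocalization with the CN signal.
* **Drift.** Each plane after the first is translated by an integer
  shift drawn uniformly in ±`drift_max_px` (default 3). Translation is
  rigid; no rotation, consistent with the translational drift-correction
  convention of standard SIMS processing.
* **Enrichment dynamics.** Per cell, atom fractions are normal draws
  around a quadratic-in-time median trajectory
  $c_2 t^2 + c_1 t + c_0$, clipped to $[0, 1)$, with a cell-to-cell SD
  that is non-decreasing in time (linear by default) — the generator
  counterpart of the two empirical observations the statistics layer
  targets: a smooth saturating median trend, and heterogeneity that
  grows with incubation time. `study_enrichment()` packages a labeled
  parameterization whose medians rise from natural abundance to
  $R_{13} \approx 0.037$ and $R_{15} \approx 0.014$ by 23 h, plateauing
  late; the defaults of `scene_config()` itself are *unlabeled*
  (natural abundance, zero spread), which is the correct null for
  baseline-recovery experiments.
* **Determinism.** One root seed; each (time point, replicate) scene
  derives a child seed, so any scene is reproducible in isolation and
  replicates are independent.

What the generator does **not** model: sputtering physics, detector
dead-time and quasi-simultaneous-arrival corrections, sub-pixel drift,
cell motion or division during acquisition, and 3-D depth structure.
Tests passing on synthetic scenes therefore validate the *computational
contract* (registration, masking, estimator behavior under Poisson
statistics), not instrument-specific systematics.

# Drift correction and accumulation

`estimate_drift()` scores every integer shift within ±`max_shift`
(default 10 px) by the Pearson normalized cross-correlation between the
shifted plane and plane 1 of the reference ion, computed on the overlap
region only. Ties are broken by the smaller shift magnitude, then
row-major order, making the result unique and reproducible. The
reference ion defaults to 12C14N-, the strongest biological channel; one
trace is applied to all ions because they are acquired in parallel. An
all-zero reference plane is an error (nothing to align on).

`accumulate_planes()` shifts each plane back by its estimated drift and
sums. A validity mask records pixels covered by *every* shifted plane;
outside it values are zero and flagged, and all downstream ROI statistics
use valid pixels only — out-of-footprint pixels are never zero-padded
into a ratio. At zero drift the operation reduces to a plane-wise sum
and conserves counts exactly.

Integer-pixel shifts are deliberate: interpolation would break the
Poisson nature of the counts, and per-plane drift at this raster is on
the order of a pixel.

# Segmentation and quantification

`segment_cells()` is an automatic stand-in for manual outlining: Otsu
threshold on the chosen ion (computed from valid pixels), 8-connected
components, per-object hole filling, and a minimum-area filter
(default 20 px), labels ordered by descending area. Because Otsu always
produces *a* threshold even on pure counting noise, a contrast guard
(foreground/background mean ratio, default 2) classifies low-contrast
scenes as cell-free instead of shattering them into spurious ROIs.
Manual masks can be substituted via `read_roi_masks()` at any point.

`measure_cell()` pools counts over the ROI (ratio of sums, not the mean
of per-pixel ratios — the standard estimator for count-limited SIMS
data, and the one that is nearly unbiased once the denominator sum
reaches ~10^4 counts). The 15N/14N ratio is taken as exactly the
CN-channel sum ratio with no correction factor. Both the raw ratios and
the APE transform are reported; downstream statistics default to ratios,
with APE available, since the two scales are used interchangeably in
this literature and differ only by a monotone transform and baseline
shift.

`rod_morphometrics()` takes the principal axes from the second central
moments of the mask pixel coordinates; length and width are the extents
of the projected pixel centers plus one pixel, times the pixel size. The
+1 convention makes a single-pixel object one pixel long rather than
zero. Rotation changes either extent by at most about one pixel
(rasterization error).

Crystal morphometrics are table-based (crystals are measured manually on
TEM images in practice): `crystal_summary()` reports the fixed 10-nm-bin
length histogram, length mean ± SD, mean shape factor (width/length),
and the OLS width-on-length regression with Pearson r, which separates
isotropic from anisotropic (length-dominated) crystal growth.

# The statistical layer

**Normality gate.** Each dataset is tested with Shapiro–Wilk; it is
"normal" iff p > 0.05. `compare_groups()` then applies an unpaired
two-sided Student t-test with pooled variance when both groups pass, and
a two-sided Mann–Whitney U otherwise, significant at p < 0.05. The U
test uses the normal approximation with continuity correction because
count-derived ratios tie frequently. No multiple-testing correction is
applied by default (a Holm-adjusted column is opt-in in
`compare_timepoints()`).

**Subsample-median bootstrap fit.** `bootstrap_polyfit()` estimates the
time trend of a per-cell variable: per repetition, sample
$\lceil 0.7\,n_g \rceil$ cells per time point (without replacement by
default — "70% of the data" describes a subset; a classical
with-replacement mode is a switch), compute per-time-point medians, and
least-squares-fit a second-order polynomial to (time, median). After
10,000 repetitions each coefficient's empirical distribution is binned
with Freedman–Diaconis widths and the modal bin center is the reported
coefficient; a joint (3-D) mode is available behind a flag but the
per-coefficient mode is stabler at this repetition count. The RSS is
evaluated against the *full-data* per-time-point medians (eight
residuals), since the medians are the fit's targets. Degenerate cases
are exact: noiseless data make every repetition identical, the
"histogram" collapses to the common value, and RSS is zero; with
fraction 1 and one repetition the procedure is exactly a single
least-squares fit of the medians.

A caveat worth stating precisely: subsampling 70% of a *fixed* sample
without replacement shrinks the dispersion of the subsample median below
the true sampling dispersion of the full-sample estimate (by roughly
$\sqrt{1/0.7 - 1} \approx 0.65$ here), so the subset variant's
coefficient histogram is a mode-stabilization device, not a confidence
distribution — its central 95% interval under-covers. Where an interval
with frequentist meaning is needed (e.g. checking that an estimated
coefficient sits within resampling noise of a known value), the
with-replacement mode supplies it; the package's own recovery tests use
that mode for coverage checks and the default subset mode for the modal
point estimate.

**Heterogeneity.** `heterogeneity_profile()` reports per-time-point IQR,
median-normalized IQR, and n, and summarizes the trend as the Spearman
rank correlation of IQR with time; a constant or undersized profile
reports 0 with an explicit flag rather than NA or silence. Undersized
groups are flagged, never dropped silently.

# Numerical and design choices

* Medians of even-sized samples are the midpoint of the central order
  statistics (R's default), including inside the bootstrap.
* The polynomial is fitted via an explicit Vandermonde design and a
  normal-equations solve; with times up to 23 h and order 2 the system
  is well conditioned.
* Coefficient histograms with numerically degenerate ranges (relative
  range < 1e-12) report the common value exactly instead of a bin
  center.
* Drift NCC candidates with constant overlap are scored $-\infty$;
  plane 1's shift is (0, 0) by construction.
* Pixel coordinates are (row, col), 0-based in the on-disk convention,
  row increasing downward; all modules share it.
* Serialization: per-ion multi-page TIFF (16-bit, or 32-bit when counts
  exceed 65535) + JSON sidecar; CSV measurement tables with a fixed
  column order; readers reject malformed input rather than coercing.

# Problem sizes used in the test suite

The suite validates geometry and estimator contracts on 64-px scenes
with 1.8–2.6 um rods (fast, exact), and the end-to-end
natural-abundance recovery on ten full-size 256-px scenes of five cells
each (50 cells), where the mean per-cell $R_{13}$ and $R_{15}$ must land
within 2% of 0.0112 and 0.0037. Bootstrap recovery runs 20 seeded
datasets of 40 cells per time point at 10,000 repetitions; test
calibration uses 2,000 null repetitions per scenario. These sizes give
each check comfortable statistical resolution relative to its tolerance.

# Known limitations

* Automatic segmentation assumes well-separated cells on a dark
  background; touching cells merge (the instrument workflow this mirrors
  outlines cells manually, and manual masks are supported).
* The ratio estimator's near-unbiasedness is a high-count property;
  below ~10^3 denominator counts per cell the ratio-of-sums bias and
  skew grow.
* The quadratic trend is descriptive, not kinetic; extrapolation beyond
  the fitted time range is meaningless.
* Printed headline statistics of any particular real dataset (RSS
  values, cell-length means, crystal means) are functions of raw images
  this package does not ship; the pipeline reproduces the *procedures*,
  and its tests validate them against synthetic ground truth.
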