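# stepkymo

Quantification of stepwise Erk-activity-border regression in the
zebrafish presomitic mesoderm (PSM) from FRET ratio time-lapse movies.

During somitogenesis, FGF/Erk signalling forms a step-like gradient in
the PSM with a sharp anterior border that retreats posteriorly in
discrete jumps. The timing of those jumps is clocked by the
segmentation clock: in control embryos the inter-step intervals are
tight (≈ 29 min, CV ≈ 0.16), while in clock-deficient (*her1;her7*
knockdown) embryos they are broad (≈ 37 min, CV ≈ 0.34) and the
resulting somites vary in size in proportion to the interval that
produced them. `stepkymo` is for imaging labs and modellers who want
that analysis as a tested, scriptable pipeline rather than a chain of
GUI tools.

The measurement chain:

- **FRET ratio imaging** — `compute_ratio()` (YPet/CFP with a validity
  mask), `median_filter_frames()` (mask-aware 15×15 median, in C++),
  `roi_mean_series()`, `imd_render()` (3/8-colour intensity-modulated
  display; the border is the white mid-ratio colour), and
  `ttest_one_tailed()` (pooled Student's t, significance at P < 0.01).
- **Kymograph and border** — `build_kymograph()` (16-px band average
  along an anterior–posterior line of interest), `extract_isolines()`,
  and `select_border()`, which picks the isoline with the largest
  velocity variance: a drifting isoline has constant velocity (zero
  variance), a stepping border alternates stalls and jumps.
- **Change points and intervals** — `detect_change_points()` finds the
  peaks of the negative Savitzky–Golay second derivative of the border
  velocity (the velocity of a stepping border is a spike train, and
  the velocity's negative curvature is maximal at each spike);
  `sequential_intervals()`, `all_pairs_intervals()` (lag-annotated),
  `interval_stats()` (mean, SD, CV = SD/mean), `periodicity_estimate()`.
- **Tracking and somites** — `detect_spots_movie()`,
  `retrograde_track()` (greedy gated nearest-neighbour, backwards in
  time), `border_overlap()` (the "coincides with the border for ≥ 5
  min" criterion), `somite_sizes_from_border()` (plateau differences,
  each paired with its bounding step interval), and
  `interval_size_correlation()` — the OLS fit of somite size against
  the preceding interval, whose slope estimates the wavefront speed
  $v$ in size $= v \cdot \Delta t$.
- **Simulation** — `sim_config()` / `regime_preset()` /
  `build_truth()` / `render_ratio_movie()` / `render_channels()`: a
  clock-and-wavefront generator (renewal-process step times, border
  jumping onto a wavefront drifting at 1.65 µm/min, sigmoid ratio
  field, nuclear spots) with full ground truth for validation.

Results are tibbles (with `tidy()` / `glance()` / `autoplot()`
methods), so everything composes with dplyr and ggplot2.

## Worked example

Simulate a control-regime embryo (240 min at 5-min frames, interval
29.4 ± 4.6 min, wavefront 1.65 µm/min) and run the full chain:

```r
library(stepkymo)

cfg <- pipeline_config(seed = 3, regime = "control")
run <- run_pipeline(cfg, "control_run")
run
#> <stepkymo_run> 8 change-points, interval mean 29.3 min (CV 0.12), 7 somites
#> Somite size ~ step interval: slope 1.278 um/min, intercept 10.00 um, r = 0.850 (n = 7)

run$interval_stats
#> # A tibble: 1 × 4
#>   mean_min sd_min    cv     n
#>      <dbl>  <dbl> <dbl> <int>
#> 1     29.3   3.45 0.118     7

glance(run$border)
#> # A tibble: 1 × 4
#>   level velocity_variance n_candidates n_frames
#>   <dbl>             <dbl>        <int>    <int>
#> 1  1.38              12.5            3       49

run$periodicity
#> # A tibble: 1 × 4
#>   period_min regularity lag_consistency n_lag1
#>        <dbl>      <dbl>           <dbl>  <int>
#> 1         30      0.882           0.179      7
```

Reading this: the border selector chose the isoline at ratio level
1.38 (an intermediate activity level; 3 candidates were scored) and
the detector found 8 steps whose sequential intervals average
29.3 min with CV 0.12 — the generator drew them from the 29.4 ± 4.6
control distribution, and the 5-min frame grid quantises the detected
times. The recovered period (median lag-1 interval) is 30 min, one
frame interval's resolution around the true mean. The size~interval
fit over one embryo's 7 somites has slope 1.28 µm/min and r = 0.85;
pooling embryos (as the acceptance script does) tightens the slope
toward the true wavefront speed 1.65 µm/min. `run_pipeline()` also
writes every stage's CSV/JSON (border trajectory, change points,
lag-annotated intervals, tracks, overlaps, somites, statistics) plus a
manifest with MD5 hashes to the output directory, and
`autoplot(run$kymograph)`, `autoplot(run$border, run$change_points)`,
`autoplot(run$intervals)` and `autoplot(run$somites)` draw the
standard figures.

A thin command-line wrapper is included at `inst/cli/stepkymo.R`:

```sh
Rscript inst/cli/stepkymo.R run-all --seed 3 --regime control --out control_run
```

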