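---
title: "Quantifying stepwise Erk-border regression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stepwise Erk-border regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepkymo)
```

## The measurement problem

During zebrafish somitogenesis, FGF/Erk signalling forms a step-like
activity gradient in the presomitic mesoderm (PSM) with a sharp
anterior border. Live FRET imaging of an Erk biosensor shows this
border retreating toward the posterior not smoothly but in discrete
jumps; in control embryos the jumps are clocked regularly
(intervals about 29 min at 28.5 °C), while in clock-deficient
(*her1;her7* knockdown) embryos they occur at irregular times and the
resulting somites are irregularly sized in proportion to the interval
that produced them. `stepkymo` turns that observation into a
reproducible measurement chain:

1. **ratio imaging** — acceptor/donor (YPet/CFP) division with a
   validity mask, 15×15 median filtering, circular-ROI time series,
   intensity-modulated display rendering, and the one-tailed pooled
   *t*-test used for inhibitor comparisons;
2. **kymograph + border** — band-averaged kymographs along an
   anterior–posterior line of interest, isoline extraction, and
   selection of the border as the isoline with the largest velocity
   variance;
3. **change points + intervals** — Savitzky–Golay-based detection of
   the step times, sequential and all-pairs interval distributions,
   mean/SD/CV summaries and a median-based periodicity estimate;
4. **tracking + somites** — retrograde nearest-neighbour tracking of
   nuclear spots, border-overlap scoring, somite sizes from border
   plateaus, and the ordinary-least-squares size~interval fit;
5. **simulation** — a clock-and-wavefront generator that produces
   ground-truth movies with known step times, plateau positions,
   somite sizes and cell tracks, so every stage above can be validated
   end to end.

No raw embryo movies are distributed with the package; the generator
is the package's test bed and reference workload.

## The generative model

The wavefront drifts posteriorly at constant speed,
$w(t) = w_0 + v\,t$ (default $v = 1.65$ µm/min, $w_0 = 60$ µm). Step
times form a renewal process: inter-event gaps are i.i.d. draws from a
truncated normal (default) or moment-matched gamma distribution,
truncated below at the frame interval so every gap is positive and in
principle resolvable. The control preset uses mean 29.4 min, SD
4.6 min; the clock-deficient preset mean 36.9 min, SD 12.5 min with
3 µm somite-size noise. At each step time $t_i$ the border jumps onto
the wavefront, so the plateau positions are
$b_i = w_0 + v\,t_i + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma_s)$, and somite $i$ — bounded by
plateaus $i$ and $i+1$ — has size $b_{i+1} - b_i$. With
$\sigma_s = 0$ the size–interval map is exactly linear through the
origin with slope $v$; this is the package's strongest internal
oracle, and it also means the model *couples* size variability to
interval variability (size CV = interval CV in the control preset).
In real control embryos somite sizes are reported to be more regular
than the measured intervals; that decoupling is not representable in
this one-parameter wavefront model and is a known limitation.

The rendered ratio field is a logistic sigmoid in the
anterior–posterior coordinate $x$ (columns; position increases
posteriorly, so border regression is a position increase):

$$R(x, t) = R_\mathrm{low} + (R_\mathrm{high} - R_\mathrm{low})\,
  \mathrm{logistic}\!\left(\frac{x - b(t)}{\lambda}\right) + \eta,$$

with border length scale $\lambda = 5$ µm, ratio levels 1.0/2.0, and
i.i.d. Gaussian imaging noise $\eta$ (default SD 0.05, i.e. 5 % of
the ratio step). Raw channels are rendered as CFP = constant baseline
and YPet = ratio × CFP, so `compute_ratio()` inverts the renderer
exactly when noise is off. Default geometry is a 64×512 px field at
1 µm/px imaged every 5 min for 240 min (~8 control steps) — small
enough that a full simulated embryo is analysed in a few seconds on
one core, which is the problem size used throughout the tests and the
acceptance script (10 embryos per regime there).

**Cells.** Tracked cells are static in the PSM-anterior reference
frame, optionally with per-frame Brownian jitter, and are placed with
a minimum separation of $4\sigma_\mathrm{spot}$ (nuclei exclude each
other physically; unresolvable spot pairs would make any
nearest-neighbour tracker ambiguous). The static-cell choice is
deliberate: the border jumps *onto* the advancing wavefront, so a
cell co-moving with the wavefront would never be overtaken by the
border, whereas in the imaging frame boundary cells are observed to
keep near-constant positions while the border sweeps past them. With
`cells_on_boundaries = TRUE` cells sit exactly on the somite-boundary
plateaus, which is the configuration that reproduces the
retrograde-tracking observation: a boundary cell coincides with the
border for the full duration of its plateau, hence for at least one
frame interval (5 min).

What the generator deliberately leaves out: photobleaching and
spectral bleed-through, 3-D geometry and z-drift, cell division and
neighbour exchange, curvature of the PSM axis, and tissue mechanics.
Tests passing on generated movies therefore demonstrate correctness
of the *measurement chain*, not robustness to every artefact of live
microscopy.

## Numerical choices that matter

**Median filter.** "15-pixel window" is implemented as a 15×15
square per frame (the 2-D default of the commercial tool the
workflow replaces), with reflect padding to avoid darkening at frame
edges and a mask-aware median (masked pixels are excluded from every
window). It is implemented in C++ because a float-exact masked 2-D
median exists in no installed R package.

**Kymograph and isolines.** Each kymograph sample averages the valid
pixels of a 16-px perpendicular band (2 × `band_halfwidth_px`). Lines
of interest are restricted to axis-aligned straight lines, where the
perpendicular band is pixel-exact; synthetic fields are axis-aligned
by construction. Isoline levels default to 9 values evenly spaced
between the 2nd and 98th percentile of the kymograph; "intermediate
activity" means the middle 3 levels. Crossings are linearly
interpolated per time row; multiple crossings resolve by continuity
(nearest to the previous frame; most posterior in the first frame,
the border being the anterior limit of the posterior high-activity
domain). Interior gaps of at most 2 frames are interpolated; a level
crossed in under half the rows is unusable. The border is the usable
intermediate isoline with the largest velocity variance — a
constant-velocity drift has zero velocity variance while a staircase
alternates stalls and jumps — with exact ties going to the lowest
level.

**Change points.** The border velocity (forward difference, computed
in kymograph image space) is taken to its smoothed second derivative
with a Savitzky–Golay filter (window 5 frames = 25 min, order 2; the
window must stay below the ~6-frame control period so adjacent steps
remain separable). Peaks of the *negative* second derivative of the
velocity are the change points: the velocity of a stepping border is
a train of near-delta spikes, and the negative curvature of the
velocity is maximal exactly at a spike. We verified the plausible
alternative — convexity peaks of the *position* — mislocalises by
half a window ((window−1)/2 frames) on ideal staircases, which is why
the velocity-curvature form is used. A detected spike between frames
$k$ and $k+1$ is reported at $k+1$, the first frame of the new
plateau, which makes noiseless recovery exact to the frame. Three
guards keep the peak picking honest: a 3-point running median on the
position (exact on staircases, removes single-frame outliers;
`endrule = "keep"` so a jump into the final frame survives), a noise
floor at 3σ of the curvature noise with σ propagated from a robust
MAD estimate of the velocity noise through the filter gain, and a
relative threshold at 25 % of the largest peak's height and
prominence. Peaks closer than 2 frames merge to the earlier one.
Replicate-padding of the velocity before filtering lets steps at
either end of the record form well-shaped extrema.

**Somites and the fit.** Plateau $i$ is the median border position
over the interior frames between change points $i$ and $i+1$ (the
span after the last change point counts as a plateau too); somite $i$
is the difference of plateaus $i$ and $i+1$ and is paired with the
interval $T_{i+1} - T_i$ between the change points that set its
boundaries. A step landing on the final frame leaves its plateau
unobservable and that somite record is skipped with a warning.
Degenerate fits are defined explicitly: identical intervals give an
error (slope undefined), constant sizes give slope 0 and Pearson
r = 0.

**Tracking.** Spot detection is Gaussian smoothing (separable
convolution, edge replication) followed by 8-neighbour local maxima
with sub-pixel quadratic refinement. Linking is greedy
nearest-neighbour backwards in time, gated at `max_disp_um`
(default 10 µm/frame) with each detection claimed at most once per
frame — fully deterministic, adequate at the synthetic densities, and
a faithful stand-in for manual backward tracking. Border overlap uses
a 5 µm tolerance (about one cell radius); a run of $m$ coincident
frames scores $(m-1)\,\Delta t$ minutes, so a two-frame coincidence
at 5-min frames is the "maintained for 5 min" criterion.

**t-test.** Student's equal-variance test (not Welch's) because that
is the named procedure; it delegates to `stats::t.test(var.equal =
TRUE, alternative = "greater")` with zero-variance edge cases defined
by convention (equal constant samples: p = 0.5). Significance is
called at P < 0.01.

**Reproducibility.** Every stochastic element is seeded explicitly;
renderers derive their noise streams from the ground truth's seed, so
the same seed gives bit-identical ground truth, movies and outputs.
Pipeline CSV/JSON values are written at 9 significant digits with
unit-bearing column names, and each run emits a resolved-config copy
and a manifest with MD5 hashes of all outputs. TIFF movies are stored
as 32-bit samples normalised to the value range recorded in a JSON
sidecar; storage quantises to one part in $2^{32}$ of the range,
which is the documented round-trip accuracy.

## Open choices made here

- The interval distribution family is not observable from a printed
  mean ± SD; truncated normal is the default (matches both moments,
  guarantees positivity after truncation at the frame interval) and a
  gamma alternative is provided.
- Somite-size noise is additive Gaussian on plateau positions — the
  simplest mechanism that produces a non-zero intercept in the
  size~interval fit without breaking plateau ordering.
- Per-embryo parameter jitter is not modelled: only summary statistics
  are available to calibrate against, so all simulated embryos of a
  regime share parameters and differ only by seed.
- The number of isoline levels and the "intermediate" band are
  configuration, and the selection report records every candidate's
  velocity variance, since the original analysis does not state a
  numeric rule.
- Somite sizes are measured along the line of interest (1-D
  anterior–posterior convention), not as 2-D Euclidean
  boundary-to-boundary distances.

## Known limitations

- Steps closer than 2 frames (10 min at the default frame interval)
  merge into one detected change point; this is a sampling limit, not
  a tuning choice. Merged steps keep the size~interval pairs on the
  wavefront line (both the interval and the size sum), so the
  correlation analysis degrades gracefully.
- Because the model ties sizes to intervals exactly, the control
  regime's somite-size CV equals its interval CV (≈ 0.16); the
  generator cannot reproduce a size CV below that without a clock
  mechanism that corrects boundary placement.
- The isoline border carries a constant offset from the true border
  when the selected level is off the sigmoid midpoint; plateau
  *differences* (sizes) cancel the offset, absolute positions retain
  it (sub-pixel at the default sharpness).

## A minimal session

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 3, regime = "control")
run <- run_pipeline(cfg, "control_run")

run$interval_stats          # mean / SD / CV of sequential intervals
glance(run$border)          # selected isoline level, velocity variance
tidy(run$intervals)         # per-lag interval summary
glance(run$fit)             # size ~ interval slope, r

autoplot(run$kymograph)
autoplot(run$border, run$change_points)
autoplot(run$intervals)
autoplot(run$somites)
```
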