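---
title: "Modelling thermal germination niches from thermogradient-plate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal germination niches from thermogradient-plate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgpgerm)
```

## The problem

A bidirectional thermogradient plate (TGP) crosses a temperature gradient in
one direction with a second gradient at right angles, so a k × k grid of cells
spans every combination of a "day" and a "night" temperature between the
plate's cold and warm settings. Seeds sown across the grid and scored over time
yield, per cell, a cumulative germination series at one (day, night)
temperature regime. The goal is to turn those series into a continuous
*thermal germination niche* — the probability of germination as a smooth
function of day and night temperature — and then to read that surface through
a monthly climate series to predict when, during the year, a site's
temperatures favour germination, now and under projected warming.

`tgpgerm` implements that workflow end to end: plate design, ingestion,
regularization of irregular scoring dates, germination indices, candidate
surface models, resampling-based model selection, climate lookup, and
visualization, plus a synthetic generator with known ground truth used to
validate the whole chain.

## Plate designs and the half grid

Because day temperature is at least night temperature in any natural diurnal
regime, only cells on or below the plate's diagonal are informative. For k
cells per axis the usable half grid has k(k + 1)/2 cells: 21, 36 and 45 cells
for k = 6, 8, 9. `make_half_grid(axis_cells, cold_setting, warm_setting)`
builds the design with nominal cell temperatures linearly spaced between the
settings; `set_cell_temperatures()` substitutes measured temperatures (plates
rarely achieve their nominal gradient exactly, so analyses should use logged
cell means). `min_seed_requirement()` gives the seed budget, e.g. 360 seeds
for an 8-axis design at 10 seeds per cell.

## From scoring sheets to daily series

`cell_series()` holds one cell's cumulative counts at its scoring days and
validates monotonicity, bounds, and the viability adjustment: the denominator
of every proportion is `viable_n = round(n_sown * viability)`, the viable-seed
count estimated from a cut test or tetrazolium assay, so that a cell in which
every viable seed germinates scores 1 rather than the viability fraction. If
the observed count exceeds `viable_n` the viability estimate was too low; the
package resets it with a classed warning rather than silently truncating data.

Scoring in practice happens "when someone is in the lab" — gaps of 3 to 14
days are common. `regularize_series()` maps a series onto a daily grid. The
`linear` method interpolates between observations. The `smooth` method fits a
penalized cubic-regression spline to the cumulative counts and adds back the
linearly interpolated residuals, so the curve is smooth between observations
yet passes exactly through every observed point; the result is then clipped to
[0, final], forced to zero at day 0, repaired to be non-decreasing, and pinned
to the observed final count (conservation: regularization never creates or
destroys germinants). `auto` (the default) uses `smooth` when at least four
scoring events exist and `linear` otherwise, with a classed fallback warning.

## Germination indices

`index_registry()` documents 22 per-cell indices; `core_indices()` computes
them from a daily series and flags which are undefined (e.g. t50 when fewer
than half of the germinants needed have appeared, all time-based indices when
nothing germinated — an important state, not an error). The t50 follows the
standard bracketing-interpolation definition in both its variants, which
differ only in whether equality at N/2 closes the left or right end of the
bracket. Synchrony is computed on integerized daily counts (it is a
combinatorial quantity); uncertainty is the Shannon entropy (bits) of the
relative daily frequencies.

## Surface models and selection

Germination across the plate is modelled as a binomial GAM: per cell,
`cbind(successes, viable_n - successes)` with a logit link, smooth functions
of day and night temperature, and REML smoothing-parameter selection via the
`mgcv` engine (an established, well-tested penalized-likelihood backend; the
package's contribution is the surrounding workflow, not a reimplementation of
spline fitting). The seed is the unit of replication, so cells are weighted by
their viable-seed counts automatically.

`default_candidates()` supplies seven specifications spanning the plausible
structures: a linear baseline, tensor-product smooths with cubic-regression,
thin-plate and shrinkage thin-plate marginals, an isotropic bivariate
thin-plate smooth, additive marginal smooths, and a pure tensor interaction.
On small plates the basis dimension can exceed what the few distinct
temperatures support; `fit_surface()` reduces `k` automatically and warns
(class `tgp_k_reduced`) rather than failing. For 21-cell plates, `k = 4` per
margin is a sensible explicit choice.

Two complementary scores drive selection. Full-fit RMSE and the Pearson
correlation between fitted and observed proportions measure in-sample
agreement. `monte_carlo_holdout()` measures out-of-sample error: repeatedly
hold out 10 % of cells (at least one), refit, and record the mean absolute
error of predicted proportions on the held-out cells; the mean over (by
default) 100 replicates, with its 2.5/97.5 percentile band, estimates
predictive error. Mean absolute error is used on the proportion scale because
it is robust to the occasional wild holdout fit on tiny training sets (RMSE is
available via `metric = "rmse"`). Replicate streams are derived from one
master seed by drawing a vector of per-replicate seeds, so runs are
bit-reproducible and the first 25 replicates of a 100-replicate run are
exactly the 25-replicate run — which is how "the mean error has stabilized"
can be checked cheaply across 25/50/100/200 replicates. The default selection
rule `min_rmse` takes the converged candidate with the lowest full-fit RMSE,
breaking ties toward fewer terms and then lexicographically; `min_mean_error`
and `manual` are available.

## Climate predictions

A `climate_series` is twelve monthly (tmax, tmin) pairs. `predict_monthly()`
evaluates the fitted surface at day = tmax and night = tmin for each month.
Temperatures outside the plate's range are clamped to the training envelope by
default — the surface knows nothing beyond the plate, so extrapolation is
opt-in (`"allow"`) or an error. Multi-model projections are combined by
`ensemble_average()` (per-month mean, standard error sd/√m); prediction bands
come from evaluating the surface at the four (mean ± se) corner combinations,
which is a conservative envelope, not a delta-method interval.
`seasonal_shift_report()` compares current and future series: the peak-month
delta is computed circularly (December to January is +1, not −11), months
within 50 % of the peak are reported as the "active" germination window, and a
flat series (range < 0.01) is flagged `no_seasonality` rather than given a
fake peak. Gridded monthly climatologies in ESRI ASCII grid format can be
sampled at a coordinate with `extract_point()` (nearest-cell lookup; a CSV
path is also supported, keeping the package free of heavy geospatial
dependencies).

## The synthetic generator

Validation needs experiments with known truth. `true_surface()` defines a
Gaussian bell g(d, n) = g_max · exp(−q/2) with q the standardized, possibly
correlated, squared distance from the optimum (μ_day, μ_night) — the simplest
smooth unimodal form able to express the archetypal plate responses: flat
broad responders, cool-restricted responders, and warm responders with a
diurnal-fluctuation preference (expressed through the correlation ρ).
`timing_model()` draws each germinant's day from a lognormal whose median
grows away from the optimum (default median 10 days at the optimum, log-sd
0.4, 30 % slowdown per unit of q). `simulate_experiment()` is per-seed:
Bernoulli viability, Bernoulli(g) germination for viable seeds, a lognormal
germination day, cumulated at the scoring days — reproducible given a seed.
`make_fixture_suite()` packages three archetypal experiments with current and
eight-model future (+5 °C with inter-model jitter) climate series.

Realism limits worth noting: the generator has no dormancy, no after-ripening,
no viability loss over time, independent seeds (no within-dish correlation),
and a single unimodal optimum. It validates the pipeline's estimation
machinery, not the full biology.

## Numerical and design choices

- **Rounding.** `viable_n` uses R's round-half-even; documented, tested, and
  stable across platforms.
- **Quilt plots** interpolate cell values piecewise-linearly over a Delaunay
  triangulation of the cells, masked to their convex hull — never
  extrapolated. The triangulation is computed internally (plates have at most
  a few dozen cells, so the simple incremental algorithm suffices). Every
  figure's gridded values are exported as a CSV twin; no number exists only in
  an image.
- **Known limitation — peak attenuation.** Penalized smoothers shrink sharp
  peaks toward the mean, and the true optimum rarely coincides with a lattice
  cell, so the estimated maximum germination probability is biased slightly
  downward (a few hundredths at 45 cells × 50 seeds) even when the optimum's
  *location* is recovered essentially always. Treat fitted maxima as
  conservative.
- **Problem sizes.** The package is tuned for 21–45-cell plates with 10–50
  seeds per cell; everything runs in seconds except Monte Carlo holdout
  (seconds to a minute depending on `reps`).

## End-to-end use

`run_pipeline(run_config(...))` (or the `exec/tgpgerm` CLI: `simulate` writes
a fixture suite, `run` executes a YAML-configured analysis) performs
ingest → indices → candidate fits → holdout evaluation → selection → quilt
plots → climate predictions, writing every table as CSV, figures as PNG, a log
with the package version and seed, and a JSON snapshot of the configuration.
Rerunning the same configuration and seed reproduces the CSV outputs exactly.
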