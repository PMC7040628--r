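---
title: "Models and methods behind xylokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xylokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylokin)
```

This vignette records the modelling assumptions, parameter defaults, and
design decisions in `xylokin`, in the spirit of a methods section: what is
estimated, under which conventions, and what the choices buy and cost.

## The data and the time axis

The unit of observation is a microcore census: for one tree on one sampling
day, the number of cambial, enlarging, wall-thickening and mature tracheids
counted along each of (typically three) radial files. Counts are integers
per file; all modelling uses the per-tree arithmetic mean over files, so
the working response is continuous (a third of a cell is meaningful as an
average).

Time runs on a single **season day** axis: days since January 1 of the
season's start year (Jan 1 = day 1), continuing past 365 when the campaign
crosses into the next calendar year. A Mediterranean season sampled from
late winter to the following spring spans roughly days 60–430 on this axis.
Keeping one monotone axis avoids every special case at the year boundary.

## Smoothing seasonal count curves

Each group × phase series is fitted with a penalized cubic regression
spline of the mean count on season day plus a random intercept per tree
(`mgcv`, REML-free: the smoothing parameter is selected by generalized
cross-validation). Defaults: basis dimension 10, Gaussian family, 95%
pointwise bands, daily prediction grid.

Choices worth stating explicitly:

* **Gaussian, not Poisson.** Averaging over radial files makes the response
  fractional, and the seasonal signal-to-noise of phase counts is high; a
  Gaussian working model on the averaged counts is the simplest defensible
  reading. The family is configurable (`smooth_config(family = "poisson")`
  fits on the log link and returns response-scale bands).
* **Random intercept only.** Tree identity enters as a random level shift;
  no random smooths. With five trees per group there is little information
  for anything richer, and the population curve is the target.
* **No constraint to positive counts inside the fit.** Clipping inside the
  optimizer would bias the standard errors; fitted values are clipped at
  zero only for reporting and before the kinetics inversion.
* **Pointwise, not simultaneous, bands.** Group differences are read off as
  windows where two groups' pointwise bands are disjoint, with window
  endpoints refined by linearly interpolating the band gap to its zero
  crossing. This is a deliberately conservative, assumption-light contrast:
  no joint model, no interaction smooth, and the comparison logic is
  symmetric in the two groups.
* **Penalty limit.** The cubic-regression-spline penalty annihilates
  straight lines, so forcing the smoothing parameter to infinity drives the
  fit to the least-squares line (whose average equals the group mean on a
  balanced design), not to a constant; the test suite asserts exactly this
  limit.

A fit requires at least `max(6, basis_dim)` distinct sampling days; fewer
raises an informative error rather than a silently under-determined fit.

## Inverting counts into kinetics

The inversion rests on one ordering fact: a cell that has reached a later
differentiation phase has passed through all earlier ones. Hence the number
of cells having *entered* enlargement by time t is `E(t) + L(t) + M(t)`,
wall deposition `L(t) + M(t)`, and maturity `M(t)`. From the fitted curves
these cumulative curves are built after clipping negatives, then
monotonized by **running maximum**. The running maximum (rather than, say,
isotonic regression) preserves the first-crossing times of the increasing
envelope, which is exactly what entrance dates are; the package reports the
maximum distortion this repair introduced as a conservation diagnostic
(`C_E − C_L` must reproduce the standing enlarging count wherever nothing
was repaired).

Cell *i*'s entrance date is the first crossing of level *i*, linearly
interpolated between grid points; with a daily grid the interpolation error
is negligible. Whole cells only: fractional final levels are dropped — a
cell either forms or it does not. Residence durations follow by
subtraction; cells that never mature within the season keep a missing
maturity date and missing d_T rather than an extrapolated one.

Two deliberate omissions:

* **No per-cell cambial residence time.** Without an operational criterion
  for when a cambial derivative becomes committed (distinct from entering
  enlargement), a per-cell cambial residence is not identifiable from
  counts; the cambial dynamics are reported as a rate curve instead.
* **rC definition.** The cambial division rate is, by default, the
  derivative of `C_E + max(0, N_C(t) − N_C(start))`: cells produced equal
  cells exported to enlargement plus net growth of the standing cambial
  pool. This is a documented convention, switchable to the plain export
  rate (`rc_method = "entry"`); the two coincide whenever the pool is not
  growing.

### Fit-free inversion and interval censoring

For recovery testing (and for quick looks at raw data) the same inversion
can bypass the smoother entirely. Raw counts are interval-censored first
detections: a census on day t only reveals that a newly seen cell entered
somewhere in `(t_prev, t]`. The fit-free estimator therefore places each
entrance at the **midpoint of the interval preceding first detection**,
which bounds the error by half the sampling interval for every observable
cell — the property the recovery tests assert at both 1-day and 10-day
cadences. Cells already present at the first census are flagged `censored`:
their entry predates observation and is not identifiable.

## Tracheidograms

Relative position of a tracheid is its center distance from the ring start
divided by ring width, with cell width `LD + 2·CWT` (lumen plus both radial
walls). Profiles are resampled by linear interpolation onto the **midpoint
grid** `(i − 0.5)/n`: with n equal to the cell count and equal cell widths
the grid coincides with the cell centers and resampling is the identity —
the convention that also matches the simulator's quantile placement and the
kinetics-to-anatomy matching (cell *i* of *n* ↔ ring quantile
`(i − 0.5)/n`). Input rings must already be ordered pith→bark; the package
does not re-order or cross-date.

Earlywood/latewood classification uses Mork's index (latewood iff
4·CWT ≥ LD), the field default; the multiplier is an argument because
census protocols differ. Group trait profiles are compared with the same
spline + random intercept + band-overlap machinery as the count curves,
with relative position as the predictor.

## Phenology

Onset and cessation of a phase are the first up- and last down-crossing of
a **0.5-cell threshold** on the fitted curve — a half-cell is the natural
"is there a cell there or not" rule for curves that hover near zero outside
the active season; the threshold is configurable and the window shrinks
monotonically as it rises.

Uni/bimodality is decided from peak **topographic prominence** (≥ 0.2 of
the curve's global maximum) and **separation** (≥ 60 days): a spring and an
autumn pulse of a facultatively bimodal Mediterranean season are months
apart, while smoother wiggle produces close, low-prominence bumps. The
classification is invariant under positive rescaling, and the two highest
qualifying peaks are reported.

## The simulator

`default_paper_scenario()` encodes a three-treatment drought-manipulation
season — control, irrigation, rain exclusion; five trees per group; 10-day
sampling over season days 60–430; three radial files — with group
parameters anchored to the magnitudes such an experiment produces:

| parameter | control | irrigation | exclusion |
|---|---|---|---|
| total cells/tree | 41 | 30 | 26 |
| production | bimodal (d90 + d295) | bimodal | unimodal (d90) |
| d_E first→last cell | 20→8 d | 20→8 d | 25→10 d |
| d_T first→last cell | 20→80 d | 20→60 d | 20→120 d |
| CWT first→last | 2.5→8 µm | 2.5→8 µm | 2.5→6 µm |
| cambial pool base/peak | 6.5/10 | 6.5/8 | 5/8 |

Lumen diameter plateaus at 40 µm over the first 40% of the ring and falls
linearly to 10 µm in all groups. Cells are placed **deterministically at
quantiles** of the production mixture (cell *i* at quantile
`(i − 0.5)/n`), which is what makes exact recovery oracles possible; the
only tree-level randomness is a total-cells effect (SD 5.6 cells) and a
whole-season timing shift (SD 3 days). The 5.6-cell SD is back-computed
from the pairwise contrast such an experiment reports (a ~13-cell
control–exclusion difference significant at p ≈ 0.01 with five trees per
group implies a within-group SD near 5.6). Observation noise, when enabled,
is per-file independent thinning (each file detects each differentiated
cell with probability p), keeping counts integer and non-negative;
anatomy tables carry small Gaussian measurement noise (SD 2 µm LD, 0.4 µm
CWT) while the truth table stays noiseless.

Two honest mismatches with a real season, both consequences of simple
parametric forms:

* The spring production pulse is **compressed** (SD ≈ 13 days, starting
  after the first census) so that every cell's entry falls inside the
  observation window and recovery can be scored against a complete truth.
  A real spring pulse is skewed and two-to-three times wider; one
  consequence is that simulated peak production rates (~1 cell/day) run
  about three times higher than a field season with the same totals.
* Wall-deposition duration is **linear in formation order**, so the
  longest d_T lands on the last-formed cells, whereas in a bimodal field
  season the maximum typically belongs to mid-season cells that start
  deposition just before the summer pause.

Passing the recovery tests therefore demonstrates that the inversion and
statistics are correct under the structure the analysis assumes — not that
the smoother is unbiased on arbitrarily shaped field seasons (its boundary
bias at a 10-day cadence is visible in the worked example's first cells).

## Group-level statistics

Per-tree season totals are compared by classical one-way ANOVA with Tukey
HSD (studentized range) pairwise contrasts. Shapiro–Wilk and Levene checks
are attached as diagnostics but never gate the test. Two numerical
conventions: a response with literally no between-group variance reports
F = 0, p = 1 (rather than the 0/0 of the raw decomposition), and Tukey
p-values for zero differences in that degenerate case are 1. The Tukey
p-value dominates the *pooled-variance* pairwise t-test (same residual df);
it can undercut a two-sample t-test computed from only the two groups'
variances, which is why the dominance property is stated against the
pooled form.

Trait–duration relations (lumen diameter vs enlargement duration, wall
thickness vs deposition duration) are fitted as linear mixed models with a
random intercept per tree, by REML (standard for variance components at
small tree counts), with Wald slope intervals. A single tree collapses the
model to ordinary least squares. In the pipeline, each tracheid is matched
to the group kinetics by formation-order quantile, since kinetics are
computed on group-average curves.

## Problem sizes and determinism

The test suite and the acceptance script run the full scenario (15 trees,
38 sampling days, ~100 cells/group pipeline inversions), a 100-replicate
ANOVA power check, and a 200-replicate mixed-model recovery — sizes chosen
so the whole suite completes in well under a minute on one core while
keeping Monte Carlo error far from the asserted margins. Every stochastic
step derives from an explicit integer seed; identical configuration and
seed reproduce every output CSV byte for byte, which the tests assert.

## Known limitations

* No uncertainty propagation from the smoother into kinetics: entrance
  dates are point estimates from the mean curve. Band-based kinetics
  envelopes are a natural extension.
* Kinetics are per group, not per tree (the group-average curve is
  inverted); per-tree inversion is possible via the fit-free path but is
  noisier at census cadence.
* No autocorrelation structure in the residuals; no simultaneous bands; no
  multi-year rings or cross-dating; no climate covariates in the simulator.
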