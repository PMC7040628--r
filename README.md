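# xylokin

Kinetics of wood formation (xylogenesis) from repeated microcore cell
counts.

Intra-annual wood formation in conifers is monitored by sampling microcores
from the stem every ~10 days through a growing season and counting, along a
few radial files, the tracheids in each differentiation phase: cambial
(#C), enlarging (#E), wall-thickening/lignifying (#L) and mature (#M).
`xylokin` turns those longitudinal counts into the quantities
dendroecologists actually reason about — when each cell entered each phase,
how long it stayed there, and how fast it grew — and compares treatment
groups (e.g. rain exclusion vs control vs irrigation in a drought
manipulation experiment). It is aimed at quantitative wood anatomists and
plant ecophysiologists working with Trephor-style microcore census data.

## What it computes

**Smoothing.** For each group × phase, counts averaged over radial files
are smoothed with a penalized cubic regression spline over the season day
*t* (days since Jan 1 of the start year, continuing past 365 across the
calendar boundary), with a random intercept per tree for the repeated
measures and the smoothing parameter chosen by generalized
cross-validation:

    count_ij(t) = f(t) + b_i + e_ij,   b_i ~ N(0, σ_b²)

Pointwise bands are f̂ ± z·SE at the chosen level; two groups differ
wherever their bands are disjoint.

**Kinetics inversion.** Because a cell that has reached a later phase has
passed through the earlier ones, the cumulative number of cells having
*entered* each phase is C_E = Ê+L̂+M̂, C_L = L̂+M̂, C_M = M̂ (clipped at
zero, monotonized by running maximum). The entrance date of cell *i* into a
phase is where the cumulative curve crosses level *i*; residence times
follow by subtraction (d_E = t_thick − t_enl in enlargement, d_T =
t_mature − t_thick in wall deposition), and mean growth rates by division
against the cell's final anatomy (r_enl = LD/d_E, r_wall = CWT/d_T, µm/day).
Seasonal rate curves rC, rE, rL, rM (cells/day) are derivatives of the
cumulative curves.

**Tracheidograms.** Ring anatomy profiles (lumen diameter LD, wall
thickness CWT) are standardized to relative in-ring position (cell center
distance / ring width), resampled to a common grid, compared between groups
with the same band-overlap rule, and split into earlywood/latewood by
Mork's index (latewood iff 4·CWT ≥ LD).

**Phenology and statistics.** Onset/cessation/duration per phase
(half-cell threshold), unimodal vs bimodal classification of seasonal
curves (peak prominence + separation), one-way ANOVA with Tukey HSD on
per-tree totals, and REML mixed-model slopes of traits on differentiation
durations.

**Simulator.** A seeded forward simulator (`default_paper_scenario()`)
generates a three-treatment, five-trees-per-group season (cells placed at
quantiles of a Gaussian production mixture; linear duration and anatomy
gradients over the ring) with ground-truth timelines, used throughout the
tests to verify that the pipeline recovers what generated the data.

## Worked example

```r
library(xylokin)

scenario <- default_paper_scenario(seed = 1)
sims   <- simulate_experiment(scenario)          # counts + anatomy + truth
avg    <- average_radial_files(sims$counts)
curves <- fit_phase_curves(avg)

phen <- phenology_metrics(curves)
phen[phen$phase == "thickening", ]
#>         group      phase    onset cessation duration modality peak_days
#> 3     control thickening 71.39177  406.9457  335.554  bimodal   136;341
#> 7   exclusion thickening 75.40786  253.6949  178.287 unimodal       144
#> 11 irrigation thickening 72.01829  384.6233  312.605  bimodal   133;336

cums <- cumulative_entry_curves(curves$control)
kin  <- cell_kinetics(cums, group = "control")
nrow(kin)       # 42 cells recovered for the control group
```

Wall deposition is classified bimodal in the control and irrigation groups
(spring pulse near day 135, autumn pulse near day 340) and unimodal under
rain exclusion, which also stops ~130 days earlier — the facultative
bimodal pattern the simulator encodes. Early-ring cells enlarge longer and
deposit wall for less time than late-ring cells (here, median d_E 16.0 vs
9.7 days and d_T 38.4 vs 74.3 days for the first vs last third of the
ring; note entrance-date estimates for the very first cells carry the
smoother's boundary bias at a 10-day sampling cadence).

Treatment contrast on per-tree totals:

```r
tot <- aggregate(list(total = avg$n_enlarging + avg$n_thickening + avg$n_mature),
                 by = list(tree = avg$tree_id, group = avg$group), max)
one_way_anova(tot$total, tot$group)
#> one-way ANOVA: F(2,12) = 14.666, p = 0.000599
#> group means:
#>    control  exclusion irrigation
#>       42.4       29.6       29.0
#> Tukey HSD:
#>                  pair  diff     lwr    upr   p_adj
#>     exclusion-control -12.8 -20.257 -5.343 0.00169
#>    irrigation-control -13.4 -20.857 -5.943 0.00118
#>  irrigation-exclusion  -0.6  -8.057  6.857 0.97500
```

The all-in-one driver writes every artifact (fitted curves, significance
windows, kinetics, rates, profiles, phenology, stats, a units sidecar and
a manifest) as tidy CSV:

```r
run_pipeline(pipeline_config(sim_config = default_paper_scenario(),
                             out_dir = "out", seed = 1))
```

## Package layout

- `R/core-model.R` — schemas, CSV readers/writers, validation, season-day
  time axis
- `R/smoothing.R` — penalized-spline group curves and band-overlap
  comparison
- `R/kinetics.R` — cumulative entry curves, entrance dates, residence
  times, rate curves, fit-free recovery
- `R/tracheidogram.R` — relative-position standardization, profiles, Mork
  split
- `R/phenology.R` — phase windows, uni/bimodality
- `R/synthetic.R` — the seeded forward simulator
- `R/stats.R` — ANOVA/Tukey and mixed-model slopes
- `R/pipeline.R` — the end-to-end driver
- `vignettes/xylokin-methods.Rmd` — modelling assumptions, parameter
  defaults, and design choices
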