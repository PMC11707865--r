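---
title: "Quantifying oxythermal habitat compression and its effect on fish movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oxythermal habitat compression and its effect on fish movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxytel)
```

## The problem

Temperate eutrophic lakes stratify in summer. Microbial respiration then
consumes dissolved oxygen (DO) beneath the thermocline, which cannot be
replenished until fall turnover. A cool-water fish such as walleye is squeezed
from below by the growing hypoxic hypolimnion and from above by
warmer-than-optimal surface water. `oxytel` quantifies both sides of this
squeeze and asks whether habitat compression actually changes how much fish
move, using passive acoustic telemetry as the movement record.

The pipeline has four statistical layers, each usable on its own:

1. **Habitat accounting.** A bathymetry grid becomes a hypsographic curve
   (area and volume per 1-m depth stratum). Each day's water-column profile
   labels every stratum *hypoxic* (DO < 3 mg/L), *optimum* (DO > 5 mg/L and
   18–23 °C) or *suitable* (all remaining non-hypoxic water), and the curve
   converts labels to volumes. The three classes partition the lake exactly,
   which the tests verify to machine precision.
2. **Movement measurement.** Raw detections are QC-filtered, per-fish monthly
   movement networks are built and screened against a permutation null, and
   each surviving network is converted to a displacement distance: for every
   receiver pair, (movements) × (detection-range adjustment factor) ×
   (in-water least-cost distance), summed over pairs.
3. **Growth.** Von Bertalanffy growth functions
   \(FL = L_\infty\,(1 - e^{-K(\mathrm{age} + a_0)})\) are fitted to
   age–length surveys and used to assign ages and project fork lengths over
   the study years.
4. **Inference.** Monthly displacement is modelled against habitat
   availability with a Gamma GAMM (log link), random intercepts for fish and
   year, and AIC-ranked backward selection.

A note on vocabulary: for volume accounting the three classes are mutually
exclusive (optimum is carved out of the non-hypoxic water). As a *model
predictor*, however, "suitable habitat" means all water with DO above
3 mg/L at any temperature — the union of the suitable and optimum classes —
because that is the quantity a DO-limited fish actually has available.
`model_frame()` performs this union; the daily series keeps the partition.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| hypoxia DO threshold | 3 | mg/L | field-observed avoidance level for walleye; strict `<` |
| optimum DO threshold | 5 | mg/L | strict `>`; DO exactly at a threshold falls to suitable |
| optimum temperature band | 18–23 | °C | inclusive; field/physiological optimum for walleye |
| seasonal window | 27 May – 2 Oct | — | 129 days (leap-invariant), the profiling season common across years |
| false-positive gap | 30 × 120 | s | a detection whose nearest same-tag/same-receiver neighbour is > 3600 s away is spurious |
| minimum ping interval | tag set minimum | s | removes double-logging by overlapping receivers |
| residency filter | 0.75 | fraction of days | inclusive; a fish-month must be present ≥ 75 % of days to yield a network |
| adjustment factor clamp | [1, 5] | — | guards against pathological range ratios |
| smooth basis dimension | 5 | — | penalized cubic shrinkage splines; REML smoothness selection |
| permutation count | 1000 (200 in the pipeline driver) | — | add-one-corrected two-sided p-values |

Boundary conventions are deterministic on purpose: DO thresholds are strict
inequalities (mirroring "above 3 mg/L"), the temperature band is inclusive,
the residency threshold is inclusive, and a false-positive pair separated by
exactly the gap threshold is retained.

## Design choices where the design was open

- **Stratum volumes** use the trapezoid of the bounding areas × 1 m:
  second-order accurate and standard limnological practice. Cells with bed
  exactly at the surface are zero-depth land; no-data cells are land.
- **Daily aggregation** is mean-then-classify per 1-m stratum (one label per
  stratum-day), with linear interpolation across unmeasured strata and
  constant extrapolation at the ends, flagged. Interpolation (rather than
  dropping incomplete days) was chosen and is logged.
- **The adjustment factor** is a reconstruction. The published construction
  is not available, so the package uses the ratio of summed 50%-detection
  radii \((r^{iso}_A + r^{iso}_B)/(r^{state}_A + r^{state}_B)\): it is
  exactly 1 under isothermal conditions and up-weights movements recorded
  when coverage shrinks. It is pluggable (`factor_fun`) and recorded in the
  pipeline manifest.
- **The network null** is likewise a reconstruction: uniform shuffles of the
  fish's chronological station-visit sequence (preserving the visit
  multiset), with the number of distinct edges as statistic and a two-sided
  add-one-corrected p-value. Both the statistic and the null are pluggable.
- **Least-cost paths** run on the 8-connected water-cell lattice (orthogonal
  step = cell size, diagonal = cell size × √2) — raster-native and
  oracle-testable. On open water such paths are *octile*: up to 8.2 % longer
  than Euclidean at oblique angles, which the tests assert as the exact
  bound rather than pretending grid paths equal straight lines.
- **VBGF fitting** uses bounded Levenberg–Marquardt least squares with
  starts (1.1 × max FL, 0.3, 1). The asymptote's lower bound is 0.5 × max FL,
  *below* the largest observed fish: under realistic measurement noise
  (σ = 25 mm) the sample maximum routinely exceeds the true asymptote, and a
  bound at max FL binds and biases the growth coefficient upward of 0.04.
  Ages round to whole years, half-up.
- **The GAMM family** is Gamma with log link (displacement is positive and
  right-skewed); a Gaussian-with-log-link fallback sits behind the `family`
  argument. Random intercepts are penalized group effects (`bs = "re"`), the
  additive-model analogue of classic random intercepts. Single-level random
  factors (e.g. a one-year study) are dropped with a message. The joint
  suitable + optimum model is excluded from default rankings because the two
  predictors are derived from the same water column; `include_joint = TRUE`
  restores it, and `concurvity_check()` quantifies the overlap as the
  proportion of one term's spline-basis variance captured by projecting onto
  the other's basis span (near 0 for independent predictors, near 1 for
  deterministically related ones).
- **Selection tie-breaks**: equal AIC goes to the smaller model. The
  full-period and hypoxia-only stages are ranked separately and never
  cross-compared.

## What the synthetic generator emulates — and what it does not

`lake_scenario()` describes a bowl-shaped basin
(`depth = D (1 - (ρ/ρ_max)^p)`, default D = 25 m, area 21 km², p = 2.2 so
mean depth ≈ 13 m), a seasonal cycle (stratification onset day 150 ± jitter,
turnover day 275, epilimnion peaking near 25 °C, thermocline deepening at
0.05 m/day, hypolimnetic DO depleting at 0.12 mg/L/day), a 21-station array
whose stratified 50 % ranges (280 m vs 375 m isothermal) reproduce a ~56 %
coverage loss, and fish that transmit every 120 ± 60 s. Fish follow a
correlated random walk whose expected step length is
`step_scale × (a + b · optimum) × suitable^c` with the day's habitat
proportions, so compression suppresses movement and optimum habitat boosts
it — the effect the inference layer must recover. Spurious singleton
detections are injected to exercise the false-positive filter. One master
seed spawns every stream, so a fixed seed reproduces every table exactly.

During stratification the generator forbids re-aeration: DO at each depth is
non-increasing until turnover. This keeps the hypoxic wedge monotone (as in
observed depth–time panels) at the cost of freezing epilimnetic DO at its
midsummer minimum after the temperature peak (it stays above 8 mg/L, far
from any threshold).

The generator does **not** emulate: internal seiches and short-term
thermocline oscillation, spatially heterogeneous (3-D) oxythermal fields,
depth-structured fish behaviour, prey fields, or acoustic propagation physics
(detection ranges are inputs, not predictions). Passing tests therefore show
the *pipeline* is correct and sensitive under known dynamics; they do not
show that any particular real lake satisfies the generator's assumptions.

## Worked example

```{r example, eval = FALSE}
scenario <- lake_scenario(n_fish = 6, seed = 1)
cfg <- pipeline_config(scenario, sim_months = 5:8, n_perm = 200)
run <- run_pipeline(cfg)
run$manifest$stages$qc        # detections in/removed/retained
head(run$movement$displacement)
run$selection$table           # AIC ranking of habitat models
```

## Problem sizes and verification

The test suite validates each layer against an independent oracle: analytic
cone/paraboloid volumes (within 2 %), a hand-written exhaustive Dijkstra on
grids up to 20 × 20 (exact agreement), noiseless VBGF refits (1e-4) and
100-seed noisy refits at n = 1922 (median \(|\hat K - K| < 0.01\)),
permutation-test size at 200 null replicates (6 stations × 40 i.i.d. visits,
where the distinct-edge statistic has non-degenerate null spread; measured
rate 0.04 at α = 0.05), and an end-to-end study of 8 fish over 5 months at
10-minute steps in which pipeline-estimated displacement must rank
fish-months like the true track lengths (Spearman ρ > 0.7) and backward
selection must recover a positive habitat effect in ≥ 90 % of 50 replicates.
These sizes are the package's own validation choices and are deliberately
modest so the whole suite runs in a few minutes.

## Known limitations

- Displacement distances are relative movement indices, not swimming
  distances: a fish can be detected hundreds of metres from a receiver, and
  paths between receivers are least-cost approximations.
- The adjustment factor and network null are reconstructions (flagged above
  and in the run manifest); conclusions sensitive to either should try
  alternatives via the pluggable arguments.
- Monthly stratification state is a single label per month; lakes with
  mid-month turnover straddle two regimes.
- The residency unit is days-with-detection per month; arrays with heavy
  duty-cycling may prefer hours (not implemented).
- Emigration in the generator ends a track permanently; returning migrants
  are not simulated.
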