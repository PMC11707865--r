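# oxytel

Tools for quantifying **oxythermal habitat compression** in seasonally
stratifying lakes and relating it to fish movement measured by passive
acoustic telemetry.

In summer, a eutrophic temperate lake stratifies and the dissolved oxygen
(DO) below the thermocline is gradually consumed: cool-water fish are
squeezed between a hypoxic hypolimnion and a warmer-than-optimal epilimnion.
`oxytel` measures both the squeeze and the behavioural response:

- **Hypsometry** — a bathymetry grid (ESRI ASCII) becomes a hypsographic
  curve: lake area and volume per 1-m depth stratum.
- **Habitat accounting** — daily temperature/DO profiles label each stratum
  *hypoxic* (DO < 3 mg/L), *optimum* (DO > 5 mg/L, 18–23 °C) or *suitable*
  (remaining non-hypoxic water); the curve turns labels into daily volumes,
  monthly means and seasonal cumulative proportions over a fixed
  27 May – 2 Oct (129-day) window.
- **Growth** — von Bertalanffy growth functions
  `FL = L∞ (1 − e^(−K(age + a₀)))` fitted by bounded nonlinear least
  squares; age estimation and fork-length projection.
- **Telemetry QC** — false-positive removal (min same-tag/same-receiver gap
  > 30 × the 120-s tag delay), overlap de-duplication at the minimum ping
  interval, monthly residency and a 75 % residency filter.
- **Movement networks** — per fish-month networks (edges = counts of
  between-receiver transitions), screened against a visit-shuffling
  permutation null, then converted to displacement distances
  `Σ_pairs movements × adjustment factor × least-cost distance`, where the
  factor compensates for detection ranges shrinking under stratification and
  least-cost paths run through water only.
- **Inference** — Gamma GAMMs (log link) of monthly displacement on habitat
  availability with fish/year random intercepts, AIC backward selection and
  concurvity diagnostics.
- **Synthetic study** — a seeded simulator (basin, seasonal oxythermal
  cycle, receiver array, correlated-random-walk fish, detection model with
  injected false positives) with full ground truth, so the entire pipeline
  is testable end-to-end offline.

## Worked example

Run the whole pipeline on the built-in synthetic lake (six tagged fish,
May–August, one seed):

```r
library(oxytel)
scenario <- lake_scenario(n_fish = 6, seed = 1)
cfg <- pipeline_config(scenario, sim_months = 5:8, n_perm = 200)
run <- run_pipeline(cfg)
run
#> oxytel pipeline run
#>   simulate     n_detections=148195, n_fish=6
#>   hypsometry   n_strata=25, total_volume=275035000
#>   habitat      n_days=365, n_months=12
#>   qc           input=148195, removed_false_positive=1560, removed_dedupe=322, retained=146313
#>   spatial      n_pairs=210, n_stratified_months=5
#>   residency    n_fish_months=24, n_eligible=24
#>   networks     n_networks=24, n_significant=24
#>   displacement n_records=24
#>   model        best=optimum, n=24
```

The 25-m, 21-km² basin holds 275 × 10⁶ m³. QC removed 1560 false-positive
and 322 duplicate detections; all 24 fish-months passed the residency filter
and differed significantly from shuffled networks. Habitat compression is
visible in the monthly proportions — by August 37.5 % of the lake volume is
hypoxic:

```r
run$monthly[run$monthly$month %in% 5:8,
            c("month", "prop_hypoxic", "prop_suitable", "prop_optimum")]
#>   month prop_hypoxic prop_suitable prop_optimum
#> 5     5        0.000         0.986       0.0143
#> 6     6        0.000         0.679       0.3205
#> 7     7        0.107         0.656       0.2370
#> 8     8        0.375         0.296       0.3287
```

and in the per-fish monthly displacement (km), which shrinks as the squeeze
tightens:

```r
head(run$movement$displacement, 4)
#>   transmitter_id year month displacement_km      state     p_value
#> 1            F01 2017     5        571.2837 stratified 0.004975124
#> 2            F01 2017     6        473.1664 stratified 0.004975124
#> 3            F01 2017     7        349.0657 stratified 0.004975124
#> 4            F01 2017     8        253.5688 stratified 0.004975124
```

Backward selection ranks the habitat models by AIC (joint
suitable + optimum models are excluded by default because the two predictors
are carved from the same water column):

```r
run$selection$table
#>         model n_terms deviance_explained   aic rank
#> 1     optimum       1          9.596e+01 233.3    1
#> 2    suitable       1          9.075e+01 245.4    2
#> 3 (intercept)       0          1.167e-04 295.7    3
```

The vignette (`vignettes/oxythermal-compression.Rmd`) documents the models,
every tunable threshold, the simulator's assumptions and the package's
validation strategy.

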