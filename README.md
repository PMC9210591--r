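# adherits

Claims-based medication adherence scoring and interrupted time series
(ITS) analysis of health-system interventions.

## What problem this solves

Evaluations of discharge-prescription policies — for example, defaulting
post-myocardial-infarction patients to 90-day supplies of their
secondary-prevention cardiac medications — usually cannot randomize and
instead compare hospital groups over time using pharmacy dispensation
claims. `adherits` is for pharmacoepidemiologists and health-services
researchers running that design. It implements the full chain:

1. **Adherence scoring** — per patient and medication class, the
   proportion of days covered (PDC) over one year from discharge, with
   *sequential supply stacking* (a refill collected early starts covering
   when the previous supply runs out) and death censoring. A patient is
   *adherent* when the average PDC across the classes dispensed at their
   index fill (first fill within 7 days of discharge) is ≥ 80%.
   Per-class persistence (no ≥ 30-day uncovered run) and prolonged
   dispensation (≥ 90 days supplied at index) are scored alongside.
2. **Aggregation** — patient flags are pooled into group × discharge-month
   proportion series, with stability checks before modeling.
3. **Segmented regression with AR(1) errors** — for each group's monthly
   percentage `y_t`:

   ```
   y_t = β₀ + β₁ t + β₂ I(t > t₀) + β₃ (t − t₀) I(t > t₀) + ε_t,
   ε_t = ρ ε_{t−1} + u_t,   u_t ~ N(0, σ²)
   ```

   fit by restricted maximum likelihood (REML) with ρ profiled out.
   β₂ is the immediate (level) effect, β₃ the gradual (trend) effect, and
   the *overall effect at horizon h* is β₂ + h·β₃ — the gap between the
   fitted post-intervention response and the counterfactual extrapolation
   of the pre-intervention line. Confidence intervals use Satterthwaite
   denominator degrees of freedom.
4. **Synthetic claims generation** — a constructive simulator with
   known-truth level/trend effects, AR(1) month-level noise, 30/60/90-day
   supply mixes, refill gaps, and early deaths, so the whole pipeline is
   testable without access to restricted registry data.

## Worked example

```r
library(adherits)

cfg <- sim_config(
  n_months = 36, t0 = 24,
  groups = data.frame(group = c("intervention", "control"),
                      n_sites = c(2L, 20L), mean_monthly = c(60, 250),
                      intervention = c(TRUE, FALSE)),
  baseline_adherence_pct = 75, level_change_pct = 5,
  trend_change_pct_per_month = 0.5, innovation_sd_pct = 2, seed = 11)

run <- run_pipeline(run_config(sim = cfg))
print(run)
#> simulated 11180 patients, 256305 dispensations (seed 11)
#> scored 11179 patients; 1 excluded (no index fill); 0 orphan claims
#> adherits pipeline run
#>   outcome: adherent | months: 36 (t0 = 24) | horizon: 12
#>   retained patients: 11179 (excluded: 1)
#>   groups fitted: control, intervention
#>   effect estimates:
#>                       group          name estimate ci_low ci_high p_value   df
#> control.1           control     intercept   75.102 71.319  78.884  0.0000  7.8
#> control.2           control     pre_slope   -0.016 -0.277   0.246  0.8936  8.2
#> control.3           control  level_change    3.464 -2.546   9.474  0.2326 11.8
#> control.4           control  trend_change   -0.243 -1.008   0.523  0.4925  9.2
#> control.5           control overall_at_12    0.552 -7.552   8.656  0.8787  7.9
#> intervention.1 intervention     intercept   73.994 65.284  82.703  0.0000  6.0
#> intervention.2 intervention     pre_slope   -0.186 -0.779   0.408  0.4789  6.5
#> intervention.3 intervention  level_change   12.015 -0.510  24.540  0.0585 11.6
#> intervention.4 intervention  trend_change    0.407 -1.293   2.107  0.5919  7.4
#> intervention.5 intervention overall_at_12   16.903 -1.681  35.487  0.0678  6.1
```

Reading the output: the intervention group was simulated with a true
immediate effect of +5 percentage points and a true gradual effect of
+0.5/month, so the true overall effect at 12 months is 5 + 12 × 0.5 = 11;
this realization estimates 16.9 (95% CI −1.7 to 35.5) — 36 monthly
observations leave wide intervals, exactly as in published ITS analyses of
this size. The control group, simulated with no effect, shows an overall
estimate of 0.6 (CI −7.6 to 8.7). `run$fits[["intervention"]]` exposes the
underlying fit (coefficients, ρ̂ = 0.26, innovation variance, REML
log-likelihood), `trajectories(run$fits[["intervention"]])` the observed /
fitted / counterfactual series for plotting, and `run$process_eval$table`
the prolonged-dispensation proportions by group, class, and period.

With `outdir` set, `run_pipeline()` writes `adherence_results.csv`,
`exclusions.csv`, `monthly_series.csv`, `trajectories.csv`,
`effects_report.csv`, `process_eval.csv`, `fit_results.json`, and
`run_log.txt`. A thin command-line wrapper with `simulate` / `score` /
`aggregate` / `fit` / `report` / `all` subcommands is installed at
`inst/cli/adherits.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/adherits.R", package="adherits"))')" \
    all --seed 1 --outdir out/
```

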