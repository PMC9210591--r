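---
title: "Scoring medication adherence from claims and estimating intervention effects by segmented regression with AR(1) errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adherence scoring and interrupted time series methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Secondary-prevention cardiac medications (statins, beta blockers,
angiotensin system inhibitors, secondary antiplatelets) are recommended
long-term after myocardial infarction, yet adherence declines steadily after
discharge. Health-system interventions that lengthen the initial discharge
prescription are cheap and plausibly effective, and their evaluation
typically relies on routinely collected pharmacy dispensation claims rather
than randomization. `adherits` implements the full analytic chain for such
an evaluation: patient-level adherence scoring from claims, aggregation to
group-month proportion series, and interrupted-time-series (ITS) estimation
of intervention effects.

Aspirin is deliberately out of scope: it is available without a prescription
and is essentially invisible in dispensation claims.

## Patient-level scoring

**Index fill.** A patient enters the scored cohort through their first
dispensation within 7 days of hospital discharge. The medication classes
dispensed on exactly that day form the patient's class set (1-4 classes);
a class started later never joins the set. We read the definition of the
class set literally — "classes dispensed at the index fill" — because the
alternative (letting late-started classes join) changes the denominator of
the average PDC mid-window and makes the estimand depend on post-baseline
behavior. Same-class fills on the same day are merged by summing supply
(blister packs, split fills).

**Proportion of days covered (PDC).** For each index class, coverage is
accumulated by *sequential stacking*: supply is consumed in dispensation
order, so a refill collected before the previous supply runs out starts
covering the day that supply ends. Formally, with fills $(d_i, s_i)$ sorted
by day, the $i$-th coverage segment is $[\max(d_i, e_{i-1}),\,
\max(d_i, e_{i-1}) + s_i)$ with $e_i$ its right endpoint. All intervals are
half-open at day granularity, which makes segments compose without
off-by-one ambiguity. PDC is the covered fraction of the follow-up window
$[0, W)$, where $W = \min(365, \text{death day} - \text{discharge day})$:
death censors the window, and supply extending past the window (or past
death) is truncated, not redistributed. Fills dated before discharge are
ignored — follow-up coverage is measured from discharge.

The patient's **average PDC** is the unweighted mean of class PDCs over the
index class set, and **adherence** is average PDC $\ge$ 0.80. **Per-class
persistence** requires no uncovered run of $\ge$ 30 days inside the window;
we count the trailing run (a patient who stops 40 days before the window
end is non-persistent) and share the death-censored window with PDC, since
a definition that exempts the tail would classify every early
discontinuation as persistent. **Prolonged dispensation** is $\ge$ 90 days
supplied at the index fill, per class and as a $\ge$ 90-day average across
classes. All thresholds (7, 0.80, 30, 90, 365) are inclusive as printed and
exposed in `adherence_thresholds()`.

The interval engine is validated exhaustively against an independent
day-by-day oracle that consumes a supply bank one day at a time; the two
agree exactly on $10^4$ randomized fill configurations per test run.

## Group-month aggregation

Patients are binned by the month of *discharge*, because the cohort is
defined by discharge date ranges; binning by index-fill date would let the
exposure define the time axis. Months are equal-width bins of
365.25/12 = 30.4375 days on an integer day axis — the model treats month as
an integer index, so real calendar month lengths add nothing. Group-months
with no retained patients are recorded as missing, never as zero, and a
`stability_check()` flags series with missing months or monthly
denominators below a floor (default 10) before modeling; per-class
initial-duration series from small groups are the typical casualty. The
floor is a configuration value because no principled universal constant
exists for "too unstable to model".

## The segmented model with AR(1) errors

For one group's monthly adherence percentage $y_t$,

$$y_t = \beta_0 + \beta_1 t + \beta_2 I(t > t_0) + \beta_3 (t - t_0) I(t >
t_0) + \varepsilon_t, \qquad \varepsilon_t = \rho\,\varepsilon_{t-1} + u_t,
\quad u_t \sim N(0, \sigma^2),$$

so $\beta_0$ is the baseline percentage, $\beta_1$ the secular
pre-intervention slope, $\beta_2$ the immediate (level) effect, and
$\beta_3$ the gradual (trend, per-month) effect. The covariance of
observations at months $t_i, t_j$ is $\sigma^2 \rho^{|t_i - t_j|} /
(1 - \rho^2)$, which remains exact across gaps left by missing months — the
design keeps true calendar time and the correlation sees the true lag, so
nothing is interpolated or re-indexed.

Proportions are modeled on the linear (percent) scale without
transformation and without weighting by the monthly denominator: effects
are then absolute percentage-point changes, directly interpretable, and the
estimator matches how aggregate monthly proportions are conventionally
analyzed in ITS studies. Denominator-weighted GLS would change the estimand
toward patient-level effects and is deliberately not the default.

**Estimation.** Parameters are estimated by restricted maximum likelihood
(REML). For fixed $\rho$ the model is whitened in $O(n)$ using the Markov
property — $w_1 = \sqrt{1-\rho^2}\,z_1$, $w_i = (z_i - \rho^{d_i}
z_{i-1}) \sqrt{(1-\rho^2)/(1-\rho^{2 d_i})}$ with $d_i$ the calendar lag —
after which $\hat\beta(\rho)$ is ordinary least squares on the whitened
data and $\hat\sigma^2(\rho)$ the REML residual variance. The profiled
restricted log-likelihood (including the whitened-cross-product
log-determinant) is maximized over $\rho \in (-0.99, 0.99)$ by bounded
one-dimensional search with tolerance $10^{-8}$; convergence at the
boundary is recorded on the fit and surfaced in the run log rather than
silently accepted, because a near-unit-root $\hat\rho$ on 36 observations
usually signals a series the model should not summarize. The implementation
is cross-checked in the test suite against `nlme::gls(correlation =
corAR1())`, agreeing in coefficients, standard errors, $\hat\rho$, and the
REML log-likelihood to numerical precision, including with missing months;
`nlme` is used only as an oracle, never as the estimator.

**Effects and inference.** Intervention effects are linear contrasts
$c^\top \hat\beta$: immediate $c = (0,0,1,0)$, gradual $c = (0,0,0,1)$, and
the overall effect at horizon $h$ (default 12 months) $c = (0,0,1,h)$ —
algebraically the fitted-minus-counterfactual difference at $t_0 + h$,
where the counterfactual extrapolates $\hat\beta_0 + \hat\beta_1 t$ from
the pre-intervention data alone. Confidence intervals and p-values use a
$t$ reference with Satterthwaite denominator degrees of freedom:
$\nu = 2 v^2 / \widehat{\mathrm{Var}}(v)$ with $v = c^\top
\widehat{\mathrm{cov}}(\hat\beta)\, c$, where $\mathrm{Var}(v)$ comes from
the delta method through the observed REML information of $(\rho,
\sigma^2)$ (numerically differentiated; analytic when $\rho$ is fixed, in
which case $\nu = n - 4$ exactly). A residual-df fallback
(`df_method = "residual"`) is provided because no two mixed-model
implementations agree bit-for-bit on Satterthwaite internals. The first
post-implementation discharge month carries $I = 1$: implementation
happens between months $t_0$ and $t_0 + 1$, so the first cohort discharged
under the intervention is a post month.

Each group is modeled independently (two intervention groups, one control);
there is no between-group contrast and no multiplicity adjustment — three
separate models, reported side by side.

Simulation evidence computed by the test suite at these conditions
($n = 36$, $t_0 = 24$, $\rho \in \{0, 0.3\}$, $\sigma = 5$ percentage
points): level- and trend-change estimates are unbiased within Monte-Carlo
error (500 replicates), 95% CI coverage for the overall 12-month effect
lies inside [93.5%, 96.5%] (2000 replicates), and the type-I error of the
overall-effect test is within Monte-Carlo error of 5% (500 null
replicates).

## What the synthetic generator emulates

The real data for such a study sit in a restricted provincial claims
environment, so the package ships a generator whose output has the
statistical structure the analysis assumes, with known truth.

The generator is *constructive*: for each group and month it draws a latent
adherence percent $p_m$ = segmented trend + stationary AR(1) noise (clipped
to [0, 100]; a configuration whose baseline would clip is rejected, and
clipping in more than 1% of months triggers a warning since it biases
recovery); each discharged patient draws an adherent label with probability
$p_m/100$; and the refill trajectory is then built so the scored average
PDC lands on the intended side of 0.80 — near-continuous supply with small
refill gaps for adherent patients, supply truncated to a target coverage
fraction (uniform on [0.15, 0.70]) with larger gaps for non-adherent ones.
This makes the latent month-level proportion the exact estimand of the
downstream regression, so parameter recovery is a clean end-to-end test.
The price is realism at the refill-mechanics level: dispensing behavior is
not mechanistically modeled, and a passing recovery test says nothing about
how real refill processes map onto latent adherence. Label fidelity is not
exactly 1 — a patient who dies shortly after a late index fill can miss
the PDC target — and is asserted to exceed 99%.

Defaults are the study conditions: 36 months with $t_0 = 24$; three groups
with 2/4/143 sites and Poisson monthly cohorts of mean 39/26/515; baseline
75.3%, pre-slope 0, level change −1.1, trend change +0.54/month; AR(1)
$\rho = 0.3$ with innovation SD 5 percentage points (aggregate-noise
magnitudes consistent with reported model MSEs once binomial sampling
noise at these cohort sizes is accounted for); a 1-4 class mix with mean
≈ 2.7 classes weighted by observed class frequencies; 30/60/90-day supply
mix with 7% prolonged pre-intervention (12% post via `duration_mix_post`);
index-fill delay concentrated on days 0-2; death hazard 0.08/year, with
deaths before the sampled index delay yielding patients without an index
fill, who are excluded downstream exactly as in a real cohort. Between-site
heterogeneity within group is exposed as `site_sd_pct` with default 0: the
aggregate analysis pools sites within group, and no published within-group
site variance was available to calibrate a nonzero default.

## Numerical and degenerate-input choices

* Coverage arithmetic is integer-day and half-open throughout; merged
  same-day fills, window truncation at death, and leading/interior/trailing
  gaps are all exercised against the grid oracle.
* A noiseless series is recovered to ≥ 10 significant digits; with $\rho$
  constrained to 0 the fit reproduces the OLS closed form to machine
  precision.
* Fits require ≥ 3 observations on each side of $t_0$; fewer is an error,
  not a silent extrapolation.
* Death on the discharge day leaves an empty follow-up window and is a
  named validation error (the cohort definition requires discharge alive).
* Orphan dispensations (no matching patient) are counted, reported, and
  ignored.
* The test suite and the acceptance script size their simulations (300-2000
  replicates of 36-month series; cohorts of a few thousand patients) so the
  whole validation runs in minutes on a single core while keeping
  Monte-Carlo error well inside the asserted bands.

## Known limitations

* PDC measures possession, not ingestion; the 0.80 threshold is a
  convention carried from the outcome definition, not a clinical boundary.
* The generator's adherent/non-adherent dichotomy at the patient level is a
  modeling device; real PDC distributions are continuous with mass near 1.
* With 36 monthly observations, REML occasionally profiles $\hat\rho$ to
  the stationarity boundary on noisy small-group series; such fits are
  flagged, and their effect estimates should be read with the same caution
  the stability check applies to thin series.
* Segmented regression with an external control group adjusts for secular
  trend only through each group's own pre-period; it does not deliver a
  randomized comparison, and nothing in the package corrects for
  confounding by site selection.
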