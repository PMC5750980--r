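---
title: "Methods: heat-wave detection, excess heat load, and excess mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-wave detection, excess heat load, and excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatexcess)
```

This vignette is the package's own account of the science it
implements: the event definition, the excess-heat indices, the baseline
mortality model and its counterfactual, the excess and displacement
summaries, and the synthetic-data generator that stands in for registry
and station data. It also records the numerical and design choices made
where the method leaves them open.

## 1. Heat-wave definition

A heat wave is a maximal run of at least 3 consecutive days whose daily
mean temperature reaches or exceeds the 95th percentile of the *annual*
(all-days, all-seasons) temperature distribution, with at least one day
strictly exceeding the 98th percentile. The two-threshold form ensures
every event contains at least one genuinely extreme day; the annual
(rather than summer-only) distribution ties the thresholds to the
climate of the whole record.

Comparison operators follow the definition's wording exactly: a day
qualifies with `tmean >= t95` ("reaching or exceeding") while the
intensity day needs `tmean > t98` ("exceeding"). Both thresholds are
empirical quantiles with linear interpolation between order statistics
(`stats::quantile` type 7). The estimator choice matters only in the
third decimal on realistic series, but it is recorded in the
`hw_thresholds` object so a published threshold convention could be
matched when real station data are supplied. All calendar days,
including 29 February, enter the quantile pool equally.

Events are labelled `YYYY_k` by the calendar year of their start date
and the within-year ordinal, the labelling convention of national
heat-wave tables.

## 2. Excess-heat indices

For day $i$ with daily mean temperature $T_i$ and threshold $T^{95}$:

$$\mathrm{EHI}_{sig,i} = \tfrac{1}{3}(T_i + T_{i-1} + T_{i-2}) - T^{95}$$

$$\mathrm{EHI}_{accl,i} = \tfrac{1}{3}(T_i + T_{i-1} + T_{i-2}) -
  \tfrac{1}{30}(T_{i-3} + \dots + T_{i-32})$$

$$\mathrm{EHF}_i = \max(0, \mathrm{EHI}_{sig,i}) \times
  \max(1, \mathrm{EHI}_{accl,i})$$

The significance index measures the 3-day heat level against the
climatological threshold; the acclimatization index measures it against
what the population experienced over the preceding month. Both windows
are *backward*-looking: mortality on day $i$ responds to heat on day
$i$ and before, never after. No forward variant is offered. The EHF
floors mean it is non-negative, zero whenever the 3-day mean does not
clear the threshold, and never reduced below the significance index by
a well-acclimatized month (second factor at least 1).

**Warm-up.** $\mathrm{EHI}_{sig}$ is undefined on days 1–2 of a series
and $\mathrm{EHI}_{accl}$ (hence EHF) on days 1–32. An event whose days
include undefined indices is *rejected* by `summarize_heat_waves()`
with an explicit error rather than silently summed; `run_pipeline()`
drops such events and logs the fact. Cumulative sums over an event are
raw sums: daily $\mathrm{EHI}_{sig}$ values can be negative on the
leading days of an event (the 3-day window still contains pre-event
days) and are included with their sign. EHF is already floored daily,
so `sum_ehf` is monotone in event-day warming — warming every day of an
event by 1 °C strictly increases it, a property the test suite checks.

## 3. Direct age-standardization

Daily deaths stratified by sex × age band (default `male/female ×
0–64/65+`) are converted to rates per 10,000,000 standard population:

$$r = 10^7 \sum_a \frac{d_a}{p_a} w_a$$

with mid-year stratum populations $p_a$ and fixed standard weights
$w_a$. The default weights aggregate the European standard population
(1976 revision, the revision in use for late-20th-century Central
European mortality studies) to the two age bands: 0.89 / 0.11. Sex is
*never* standardized over: male and female series age-standardize
within sex, and single-age-band groups reduce to crude pooled rates.
Weights are renormalized within whatever group is requested, so the
same table serves all groups. Finer age bands can be supplied through
the same `(stratum, weight)` table.

## 4. Baseline mortality model

The daily baseline is a quasi-Poisson generalized additive model with
log link, fitted with `mgcv`:

$$\log E(M_i) = \alpha + s(t_i;\; \mathrm{df} = 6 \times n_y) +
  \mathrm{dow}_i + \beta\, \mathrm{hwd}_i$$

* $s$ is a **thin-plate regression spline in a continuous day index
  with fixed degrees of freedom** (`fx = TRUE`), default 6 per year of
  data. Fixing the df — rather than selecting smoothness by GCV/UBRE —
  is deliberate: 6 df/year is enough for the seasonal cycle plus slow
  trend while leaving multi-week excursions (the heat waves themselves)
  to the residual and the `hwd` term. The total df is configurable
  (`total_df`) for sensitivity analysis.
* `dow` is a 7-level factor with **sum-to-zero contrasts**, so
  $\alpha$ is a weekly-average level. Any full-rank contrast gives the
  same fit; the choice only relabels coefficients.
* `hwd` is a **single binary covariate pooled over all heat-wave
  days**. Per-event effects are a deliberate non-goal — the pooled
  coefficient is what the counterfactual baseline needs.
* Family: **quasi-Poisson**. Standardized rates are non-negative but
  non-integer, and national death counts are often mildly
  overdispersed; the quasi-likelihood fit uses the same log-link mean
  structure as Poisson while estimating the dispersion, which the model
  object reports. With no heat-wave days in a series the `hwd` term is
  dropped and $\beta$ fixed at 0 (a constant covariate would make the
  design singular).

**Counterfactual baseline.** On heat-wave days the baseline is
$\exp(\hat\eta_i - \hat\beta)$ — the fitted linear predictor with the
heat-wave-day coefficient subtracted — and the fitted mean elsewhere.
Excess mortality is therefore measured against a baseline the heat
waves did not inflate. Two exact identities follow and are tested:
baseline equals the fitted mean off heat-wave days, and equals
fitted$/e^{\hat\beta}$ on them.

Non-convergence raises an error carrying the series length and df;
`df + 10 >= n` days is rejected up front as insufficient support.

## 5. Excess mortality and Poisson limits

Daily relative mortality deviation:
$\mathrm{RMD}_i = 100\,(O_i - B_i)/B_i$ (%), requiring $B_i > 0$, which
the log link guarantees. Per event: cumulative excess
$\sum_i (O_i - B_i)$, cumulative deviation
$\sum \mathrm{RMD}$, and mean deviation
$\mathrm{\varnothing RMD} = \sum \mathrm{RMD} / \text{duration}$ — an
identity by construction, reported at 1-decimal precision.

95% limits on the excess use the exact (Garwood-type) Poisson limits
for the observed total $O$ via the count–chi-square relation,
$L = \tfrac{1}{2}\chi^2_{\alpha/2}(2O)$ (0 at $O = 0$) and
$U = \tfrac{1}{2}\chi^2_{1-\alpha/2}(2O + 2)$, shifted by the baseline
total $E$: the interval for the excess is $(L - E,\; U - E)$. This is
the narrowest reading of applying Poisson limit factors to an observed
count when the quantity of interest is $O - E$: the baseline total is
treated as fixed (it is a smooth function of thousands of days, so its
sampling variability is an order of magnitude below the event total's).
Standardized, non-integer totals are rounded to the nearest integer
*for the limit computation only*; raw values are used everywhere else.
An event is flagged significant when the interval excludes zero. The
exact limits are conservative by construction; their coverage at
moderate means sits between 94% and 96%, which the suite verifies by
simulation at mean 50.

## 6. Extended heat-wave periods and displacement

Actual heat stress starts before the thresholded event and harvesting
shows up after it, so displacement is assessed on an *extended
heat-wave period* built from the 3-day centered moving average $s_d$ of
daily RMDs:

* **EHP start** — walk backward from the event start while $s_d > 0$;
  the EHP starts at the first day of that contiguous positive run. The
  contiguous-run reading (rather than "nearest positive window
  anywhere") was chosen because it keeps EHPs connected and is the only
  reading under which EHPs of distinct events cannot overlap.
* **Positive phase end** — walk forward from the event end while
  $s_d > 0$; the phase ends at the last positive day (the centre of the
  last all-positive 3-day window).
* **Negative phase / EHP end** — continue while $s_d < 0$; the EHP ends
  at the centre of the last all-negative window. No negative day at all
  means an empty negative phase and a displaced share of 0.
* **Ties**: $s_d = 0$ *terminates* a phase (boundary-inclusive reading
  of "drop below zero"); the method statement is silent and this is the
  stricter choice.
* **Merging**: consecutive events whose separating days never have
  $s_d \le 0$ form a single EHP; the earlier events are marked absorbed
  (the `---` sentinel in the CSV report) and the merged EHP is
  attributed to the last member.
* **Cap**: both scans stop 30 days from the event (configurable), a
  guard against runaway EHPs on pathological series; on realistic
  series phases end well within it.

Displaced mortality is $100\,|\sum_{neg} s_d| / \sum_{pos} s_d$,
undefined (and flagged) when the positive-phase sum is not positive.
Relative (rather than absolute) deviations are used; with a positive
baseline the sign pattern — which is all the delimitation uses — is
identical, so the choice is cosmetic but fixed. Under pure harvesting
(every excess death advanced by a few days, equal positive and negative
mass) the smoothed sums cancel exactly and the ratio is 100%, which the
suite checks both exactly and under mild noise.

## 7. Associations between heat load and excess mortality

Per-event $\sum \mathrm{RMD}$ is regressed (OLS) on one event
characteristic at a time: $\sum$EHF, $\sum \mathrm{EHI}_{sig}$,
$\sum \mathrm{EHI}_{accl}$, average and maximum event temperature, and
duration. Reported: slope, intercept, $R^2$, two-sided slope p-value,
and a pointwise 95% confidence band. Events with undefined heat load
(warm-up overlap) are excluded listwise and counted. Group contrasts in
per-event mean RMD use a Welch (unequal-variance) two-sample t-test —
the unequal-variance form because event samples per group are small and
there is no reason to assume equal spread; with degenerate
(zero-variance) inputs the test is flagged rather than computed.

## 8. The synthetic-data generator

The generator supplies inputs with the statistical structure the
analysis assumes, and its defaults *are* the study conditions the test
suite runs under:

| parameter | default | rationale |
|---|---|---|
| annual mean temperature | 9 °C | Central European national average |
| seasonal amplitude | 10 °C | winters near −1 °C, summer means near 19 °C |
| temperature noise | AR(1), $\varphi = 0.7$, $\sigma = 2$ °C | day-to-day persistence makes multi-day exceedance runs realistic; no stochastic model is prescribed by the method, so this is a package choice |
| heat episodes | 2/summer: 4 d +6 °C (early July), 8 d +7 °C (early August) | guarantees detectable events in most simulated years while AR(1) noise varies their count and length |
| base deaths/day | 280 | a ~10.5-million population's natural-cause registry scale |
| secular trend | −0.5 %/yr | slow mortality decline |
| mortality seasonality | 0.10 (log scale) | winter-peaked cycle, peak mid-January |
| weekly cycle | Mon +3.0% … Sun −3.0% (log scale, sum-to-zero) | maximum Monday, minimum Sunday |
| heat effect | binary, $\beta = 0.10$ on heat-wave days | of the order of the ~10% average daily rise reported for national heat waves; an EHF-proportional variant (`heat_effect_type = "ehf"`) exists to exercise the heat-load association |
| population | 10.5 M; 65+ share 13% → 18% linearly | an aging population over a multi-decade record |
| death shares | 65+ carries 78.4% of deaths | national registry proportions |

Per-stratum daily counts are Poisson draws from the shared log-mean
times fixed stratum death shares; populations are mid-year (1 July)
values interpolated linearly between the start and end age structure.
Everything is reproducible from a single integer seed.

**What it does not emulate** — and hence what passing tests do *not*
establish about real data: air-pollution and influenza confounding
(excluded from the analysis scope as well), multi-station spatial
structure, cause-of-death detail below "natural causes", registry
artefacts (late registration, holiday effects beyond the weekly cycle),
and any dependence of the heat effect on age beyond proportional death
shares. Tests demonstrate that the estimators recover what the
generator injects, not that the generator is the Czech registry.

## 9. Problem sizes and numerical conventions

The test suite runs at sizes chosen to make sampling noise negligible
relative to the tested effect: 5-year series (~1,800 days) with ~300
deaths/day for model-recovery experiments, 100 seeds for the
heat-wave-coefficient coverage experiment, 50 seeds for the
association-ordering property, 1,000 random 400-day series for the
detector/oracle equivalence, and 10,000 replicates for Poisson-limit
coverage. Floating-point agreement with loop oracles is asserted at
1e-12; quantile and chi-square computations use base R's
implementations.

Degenerate inputs behave as follows: an all-constant temperature series
yields equal thresholds and no events (no day *exceeds* the upper
threshold); a series with no qualifying run yields empty event tables
and a clean pipeline exit; an event not covered by the baseline series,
a non-positive baseline, a constant regression predictor, and a
non-positive positive-phase sum each raise explicit errors or flags
rather than propagating nonsense.

## 10. Known limitations

* The displacement ratio is descriptive, not a causal decomposition;
  it inherits all ambiguity of attributing post-event deficits to
  harvesting, and values for small events are noisy.
* The exact Poisson limits treat the baseline total as fixed;
  uncertainty in the baseline fit is not propagated into the excess
  interval.
* One pooled `hwd` coefficient means the counterfactual subtracts the
  *average* heat-wave elevation from every event; unusually severe
  events therefore retain positive residual deviations (which is what
  the excess summaries then measure).
* The fixed-df spline is a modelling commitment, not a data-driven
  choice; `total_df` exists so users can probe sensitivity.
* Association regressions are univariable by design; collinearity
  among event characteristics (duration is a factor of every
  cumulative index) means their $R^2$ values are not additive
  decompositions.
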