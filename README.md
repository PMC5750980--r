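# heatexcess

Heat-wave detection, excess heat load, and excess mortality analysis for
daily national-scale time series.

## The problem

During severe heat waves, daily deaths rise well above their seasonal
level, and part of that rise is followed by a deficit as deaths of frail
individuals are merely advanced by days ("harvesting"). Quantifying how
much excess mortality a given heat wave caused — and which meteorological
property of the event best predicts that excess — requires (i) a
precise event definition, (ii) a daily mortality baseline that is not
itself contaminated by the heat waves, and (iii) summary statistics that
are comparable across years with different population age structures.

`heatexcess` implements this analysis chain for epidemiologists and
biometeorologists working with daily mean temperature and stratified
death-count registries:

1. **Heat waves** are maximal runs of at least 3 consecutive days with
   daily mean temperature `T_i >= T95` (the 95th percentile of the
   *annual* temperature distribution), at least one day exceeding the
   98th percentile.
2. **Excess-heat indices**, per day:

       EHIsig_i  = (T_i + T_{i-1} + T_{i-2})/3 - T95
       EHIaccl_i = (T_i + T_{i-1} + T_{i-2})/3 - (T_{i-3} + ... + T_{i-32})/30
       EHF_i     = max(0, EHIsig_i) * max(1, EHIaccl_i)

   The windows are backward-looking (mortality on day *i* can respond to
   past heat, not future heat). Summing the indices over an event gives
   its total heat load (`∑EHF` etc.).
3. **Direct age-standardization** of daily deaths to rates per
   10,000,000 standard population, so impacts are comparable across an
   aging population.
4. **Baseline mortality** via a quasi-Poisson GAM,

       log E(M) = α + s(time; df = 6 × n_years) + factor(dow) + factor(hwd)

   with a fixed-df thin-plate spline for trend + seasonality, a
   day-of-week factor, and a binary heat-wave-day term whose coefficient
   is then *subtracted* on heat-wave days to form a counterfactual
   baseline undistorted by the heat waves themselves.
5. **Excess mortality** per event: cumulative observed − baseline with
   exact Poisson 95% limits; relative mortality deviations
   (`RMD = 100 (obs − base)/base`), their event sum `∑RMD` and per-day
   mean `ØRMD = ∑RMD / duration`.
6. **Mortality displacement** via extended heat-wave periods (EHP):
   phases of positive/negative 3-day-smoothed deviations around each
   event; displaced share = `100 |negative-phase sum| / positive-phase
   sum`.
7. **Associations**: OLS regressions of `∑RMD` on event characteristics
   (`∑EHF`, `∑EHIsig`, `∑EHIaccl`, avg/max temperature, duration).

A seeded synthetic-data generator (`synth_config()`,
`generate_temperature()`, `generate_mortality()`) produces inputs with
the statistical structure the analysis assumes — AR(1) temperature noise
with injectable heat episodes, Poisson deaths with seasonal/weekly
cycles and a log-scale heat effect, and a drifting age structure — so
the whole pipeline is testable without registry access.

## Worked example

```r
library(heatexcess)

cfg  <- synth_config(n_years = 5, seed = 42)
temp <- generate_temperature(cfg)
thr  <- compute_thresholds(temp)
thr
#> Heat-wave thresholds (quantile type 7)
#>   95th percentile: 22.27 degC
#>   98th percentile: 24.91 degC
#>   reference period: 2000-01-01 to 2004-12-31

hws <- detect_heat_waves(temp, thr)
hws <- hws[hws$start > temp$date[1] + 32, ]   # skip index warm-up
hws <- summarize_heat_waves(hws, temp, thr)
head(hws[, c("id", "start", "end", "duration_days", "avg_tmean", "sum_ehf")], 4)
#>      id      start        end duration_days avg_tmean   sum_ehf
#>  2000_1 2000-07-05 2000-07-07             3  24.48426  15.03155
#>  2000_2 2000-08-02 2000-08-09             8  26.23239 186.14360
#>  2001_1 2001-07-05 2001-07-08             4  25.94415  53.86529
#>  2001_2 2001-08-02 2001-08-05             4  26.26359  85.52776

mort  <- generate_mortality(cfg, temp, heat_wave_days(hws))
rates <- standardize_series(mort, standard_population_default(),
                            groups = "total")
fit <- fit_baseline(rates[, c("date", "rate")], heat_wave_days(hws))
fit
#> Baseline mortality model (quasi-Poisson GAM, log link)
#>   1827 days (5.0 years), spline df = 30, dispersion = 0.818
#>   heat-wave-day effect: 0.0898 (SE 0.0090) on the log scale = +9.4%

exc <- excess_table(hws, list(total = counterfactual_baseline(fit)))
head(exc[, c("id", "excess_deaths", "ci_low", "ci_high",
             "mean_rmd", "sum_rmd", "significant")], 4)
#>      id excess_deaths ci_low ci_high mean_rmd sum_rmd significant
#>  2000_1          24.2 -25.10    77.2     3.77    11.3       FALSE
#>  2000_2         197.3 112.05   284.6    11.52    92.2        TRUE
#>  2001_1         102.9  44.49   163.7    12.78    51.1        TRUE
#>  2001_2          47.4  -8.79   106.0     6.07    24.3       FALSE
```

Reading the output: the generator injected a +10% log-scale heat effect
(`heat_effect_beta = 0.10`); the baseline model recovers it as +9.4%
(SE ~0.9%). Event `2000_2` (8 days, `∑EHF` = 186 °C) carries ~197 excess
deaths per standardized 10 million inhabitants (95% CI 112–285), a
cumulative relative deviation of 92% — i.e. ~11.5% per day above
baseline. Events whose Poisson interval covers zero are flagged not
significant.

The one-call version of all of this is
`run_pipeline(pipeline_config(...), output_dir)`, which also writes
`heatwaves.csv`, `standardized_rates.csv`, `baseline.csv`,
`excess_by_heatwave.csv`, `ehp.csv`, `association.csv`, and a run log.

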