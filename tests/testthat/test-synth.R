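zeroed_config <- function(n_years = 2, base = 300, seed = 1,
                          heat_episodes = list(), ...) {
  synth_config(n_years = n_years, temp_mean_annual = 10,
               temp_seasonal_amplitude = 0, ar1_coefficient = 0,
               noise_sd = 0, heat_episodes = heat_episodes,
               base_daily_deaths = base, secular_trend = 0,
               mortality_seasonal_amplitude = 0,
               dow_effects = rep(0, 7), heat_effect_beta = 0,
               seed = seed, ...)
}

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(n_years = 1), "n_years")
  expect_error(synth_config(ar1_coefficient = 1), "phi")
  expect_error(synth_config(base_daily_deaths = -1), ">= 0")
  expect_error(synth_config(dow_effects = rep(0.1, 7)), "sum to zero")
  expect_error(synth_config(
    heat_episodes = list(list(start = "1990-06-01", length_days = 5,
                              amplitude = 5))), "outside")
})

test_that("degenerate noise gives a constant series; seeds reproduce", {
  cfg <- zeroed_config()
  temp <- generate_temperature(cfg)
  expect_true(all(temp$tmean == 10))
  expect_equal(nrow(temp), 365 + 366)  # 2000 is a leap year

  cfg2 <- synth_config(n_years = 3, seed = 99)
  t1 <- generate_temperature(cfg2)
  t2 <- generate_temperature(cfg2)
  expect_identical(t1, t2)
  m1 <- generate_mortality(cfg2, t1)
  m2 <- generate_mortality(cfg2, t1)
  expect_identical(m1, m2)
  # a different seed changes the draw
  t3 <- generate_temperature(synth_config(n_years = 3, seed = 100))
  expect_false(identical(t1$tmean, t3$tmean))
})

test_that("injected episode raises exactly its days", {
  cfg <- zeroed_config(heat_episodes = list(
    list(start = "2000-07-01", length_days = 10, amplitude = 12)))
  temp <- generate_temperature(cfg)
  i <- temp$date >= as.Date("2000-07-01") & temp$date <= as.Date("2000-07-10")
  expect_true(all(temp$tmean[i] == 22))
  expect_true(all(temp$tmean[!i] == 10))
  # and the downstream detector fires exactly once over that window
  thr <- manual_thresholds(15, 20)
  hws <- detect_heat_waves(temp, thr)
  oracle <- detect_oracle(temp$tmean, 15, 20)
  expect_equal(nrow(hws), 1L)
  expect_equal(length(oracle), 1L)
  expect_equal(hws$duration_days, 10L)
  expect_equal(as.Date(hws$start), as.Date("2000-07-01"))
})

test_that("stratum counts sum to the total and populations interpolate", {
  cfg <- synth_config(n_years = 3, seed = 5)
  temp <- generate_temperature(cfg)
  mort <- generate_mortality(cfg, temp)
  expect_equal(nrow(mort), nrow(temp) * 4L)
  expect_true(all(mort$deaths >= 0))
  expect_true(all(mort$deaths == round(mort$deaths)))
  # per-day totals are the sum over the four strata by construction;
  # verify the long table is complete (4 strata every day)
  tab <- table(mort$date)
  expect_true(all(tab == 4L))
  # populations: constant within a calendar year, drifting across years
  m65 <- mort[mort$stratum == "male_65plus", ]
  byyear <- tapply(m65$population, format(as.Date(m65$date), "%Y"),
                   unique)
  expect_equal(length(unlist(byyear)), 3L)
  expect_true(all(diff(unlist(byyear)) > 0))  # 65+ share grows
  # stratum shares at the first day match the start structure
  day1 <- mort[mort$date == mort$date[1], ]
  expect_equal(sum(day1$population), cfg$total_population)
})

test_that("with all effects zeroed, daily counts are iid Poisson", {
  cfg <- zeroed_config(n_years = 14, base = 300, seed = 42)
  temp <- generate_temperature(cfg)
  mort <- generate_mortality(cfg, temp)
  y <- total_deaths_series(mort)$rate[1:5000]
  expect_equal(length(y), 5000L)
  # chi-square goodness of fit against Poisson(300), tail bins pooled
  brk <- qpois(seq(0.05, 0.95, by = 0.1), 300)
  bins <- cut(y, breaks = c(-Inf, brk, Inf))
  p <- diff(c(0, ppois(brk, 300), 1))
  gof <- suppressWarnings(chisq.test(table(bins), p = p))
  expect_gt(gof$p.value, 0.01)
  # mean and variance near 300 (Poisson equidispersion)
  expect_equal(mean(y), 300, tolerance = 0.01)
  expect_equal(var(y) / mean(y), 1, tolerance = 0.1)
})

test_that("weekly cycle peaks Monday and dips Sunday at large n", {
  cfg <- synth_config(n_years = 8, temp_seasonal_amplitude = 0,
                      noise_sd = 0, heat_episodes = list(),
                      mortality_seasonal_amplitude = 0,
                      secular_trend = 0, seed = 7)
  temp <- generate_temperature(cfg)
  mort <- generate_mortality(cfg, temp)
  tot <- total_deaths_series(mort)
  dow <- as.integer(format(tot$date, "%u"))
  means <- tapply(tot$rate, dow, mean)
  expect_equal(unname(which.max(means)), 1L)  # Monday
  expect_equal(unname(which.min(means)), 7L)  # Sunday
})

test_that("null heat effect leaves heat-wave days at the seasonal mean", {
  cfg <- zeroed_config(n_years = 6, base = 300, seed = 13)
  temp <- generate_temperature(cfg)
  hw_days <- seq(as.Date("2002-07-01"), by = "day", length.out = 30)
  mort <- generate_mortality(cfg, temp, heat_wave_days = hw_days)
  tot <- total_deaths_series(mort)
  on_hw <- tot$rate[tot$date %in% hw_days]
  off_hw <- tot$rate[!(tot$date %in% hw_days)]
  # difference within Monte-Carlo error (SE of the 30-day mean ~ 3.2)
  expect_lt(abs(mean(on_hw) - mean(off_hw)), 3 * sqrt(300 / 30))
})

test_that("binary heat effect scales heat-wave-day means by exp(beta)", {
  cfg <- zeroed_config(n_years = 6, base = 300, seed = 17)
  cfg$heat_effect_beta <- 0.15
  temp <- generate_temperature(cfg)
  hw_days <- seq(as.Date("2001-07-01"), by = "day", length.out = 60)
  mort <- generate_mortality(cfg, temp, heat_wave_days = hw_days)
  tot <- total_deaths_series(mort)
  on_hw <- mean(tot$rate[tot$date %in% hw_days])
  expect_equal(on_hw / 300, exp(0.15), tolerance = 0.03)
})

test_that("generator CSVs round-trip", {
  cfg <- synth_config(n_years = 2, seed = 2)
  temp <- generate_temperature(cfg)
  mort <- generate_mortality(cfg, temp)
  dir <- withr::local_tempdir()
  paths <- write_synth_inputs(cfg, temp, mort, dir = dir)
  expect_true(all(file.exists(paths)))
  tr <- read.csv(file.path(dir, "temperature.csv"))
  expect_equal(as.Date(tr$date), as.Date(temp$date))
  expect_equal(tr$tmean_c, temp$tmean, tolerance = 1e-12)
  sp <- read.csv(file.path(dir, "standard_population.csv"))
  expect_equal(sum(sp$weight[grepl("^male", sp$stratum)]), 1)
})
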