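# Stratum bookkeeping: four groups, sex x age band.
STRATA <- c("male_0_64", "male_65plus", "female_0_64", "female_65plus")

stratum_sex <- function(s) ifelse(grepl("^male", s), "male", "female")
stratum_age <- function(s) ifelse(grepl("65plus$", s), "65plus", "0_64")

#' Configuration for the synthetic temperature/mortality generator
#'
#' Bundles every tunable of the generator with validation. Defaults
#' emulate a Central European mid-latitude setting: annual mean around
#' 9 degC with a 10 degC seasonal amplitude and AR(1) day-to-day noise
#' (phi = 0.7, sd = 2 degC), a national population of 10.5 million whose
#' 65+ share drifts from 13% to 18% across the series, roughly 280
#' natural-cause deaths per day with a winter-peaked seasonal cycle, a
#' weekly cycle with maximum on Monday and minimum on Sunday, and a
#' log-scale heat effect on heat-wave days.
#'
#' @param n_years integer >= 2 (the acclimatization index needs a 32-day
#'   history and the baseline model needs multi-year seasonality).
#' @param start_date first calendar day of the series.
#' @param temp_mean_annual annual mean temperature, degC.
#' @param temp_seasonal_amplitude seasonal half-range, degC (peak around
#'   20 July).
#' @param ar1_coefficient AR(1) coefficient of the temperature noise,
#'   in [0, 1).
#' @param noise_sd innovation standard deviation of the noise, degC.
#' @param heat_episodes list of heat episodes, each a list/vector with
#'   `start` (date), `length_days`, `amplitude` (degC added on those
#'   days); use `default_heat_episodes()` for a ready-made summer set or
#'   `list()` for none.
#' @param base_daily_deaths expected deaths/day (all strata) at the series
#'   start.
#' @param secular_trend relative change in expected deaths per year.
#' @param mortality_seasonal_amplitude log-scale amplitude of the
#'   winter-peaked mortality cycle.
#' @param dow_effects 7 log-scale day-of-week offsets (Mon..Sun), summing
#'   to zero (sum-to-zero identification).
#' @param heat_effect_beta log-scale excess mortality per heat-wave day
#'   (binary form) or per unit EHF (`heat_effect_type = "ehf"`).
#' @param heat_effect_type `"binary"` (constant log offset on heat-wave
#'   days, the generative counterpart of a 0/1 heat-wave-day factor) or
#'   `"ehf"` (offset proportional to the day's excess heat factor).
#' @param death_shares named shares of expected deaths by stratum (sum 1).
#' @param age_structure_start,age_structure_end named population shares by
#'   stratum at the first and last year (each sums to 1).
#' @param total_population persons.
#' @param seed integer RNG seed; every draw the generator makes is
#'   reproducible from it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_years = 10L,
                         start_date = as.Date("2000-01-01"),
                         temp_mean_annual = 9,
                         temp_seasonal_amplitude = 10,
                         ar1_coefficient = 0.7,
                         noise_sd = 2,
                         heat_episodes = default_heat_episodes(n_years, start_date),
                         base_daily_deaths = 280,
                         secular_trend = -0.005,
                         mortality_seasonal_amplitude = 0.10,
                         dow_effects = c(0.030, 0.010, 0.005, 0.000,
                                         0.005, -0.020, -0.030),
                         heat_effect_beta = 0.10,
                         heat_effect_type = c("binary", "ehf"),
                         death_shares = c(male_0_64 = 0.1065,
                                          male_65plus = 0.3863,
                                          female_0_64 = 0.1095,
                                          female_65plus = 0.3977),
                         age_structure_start = c(male_0_64 = 0.425,
                                                 male_65plus = 0.060,
                                                 female_0_64 = 0.445,
                                                 female_65plus = 0.070),
                         age_structure_end = c(male_0_64 = 0.410,
                                               male_65plus = 0.080,
                                               female_0_64 = 0.410,
                                               female_65plus = 0.100),
                         total_population = 10.5e6,
                         seed = 1L) {
  heat_effect_type <- match.arg(heat_effect_type)
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 2L)
    stop("`n_years` must be an integer >= 2", call. = FALSE)
  if (abs(ar1_coefficient) >= 1)
    stop("`ar1_coefficient` must satisfy |phi| < 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (base_daily_deaths < 0)
    stop("`base_daily_deaths` must be >= 0", call. = FALSE)
  if (length(dow_effects) != 7L)
    stop("`dow_effects` must have length 7 (Mon..Sun)", call. = FALSE)
  if (abs(sum(dow_effects)) > 1e-8)
    stop("`dow_effects` must sum to zero", call. = FALSE)
  for (nm in list(death_shares, age_structure_start, age_structure_end)) {
    if (!setequal(names(nm), STRATA))
      stop("stratum tables must be named over: ",
           paste(STRATA, collapse = ", "), call. = FALSE)
    if (any(nm < 0) || abs(sum(nm) - 1) > 1e-8)
      stop("stratum shares must be non-negative and sum to 1",
           call. = FALSE)
  }
  start_date <- as.Date(start_date)
  end_date <- seq(start_date, by = "year", length.out = n_years + 1L)[n_years + 1L] - 1L
  for (ep in heat_episodes) {
    ep <- as_episode(ep)
    if (ep$start < start_date ||
        ep$start + ep$length_days - 1L > end_date)
      stop("heat episode starting ", ep$start,
           " lies outside the simulated date range", call. = FALSE)
  }
  structure(list(
    n_years = n_years, start_date = start_date, end_date = end_date,
    temp_mean_annual = temp_mean_annual,
    temp_seasonal_amplitude = temp_seasonal_amplitude,
    ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
    heat_episodes = lapply(heat_episodes, as_episode),
    base_daily_deaths = base_daily_deaths, secular_trend = secular_trend,
    mortality_seasonal_amplitude = mortality_seasonal_amplitude,
    dow_effects = dow_effects, heat_effect_beta = heat_effect_beta,
    heat_effect_type = heat_effect_type,
    death_shares = death_shares[STRATA],
    age_structure_start = age_structure_start[STRATA],
    age_structure_end = age_structure_end[STRATA],
    total_population = total_population, seed = as.integer(seed)),
    class = "synth_config")
}

as_episode <- function(ep) {
  list(start = as.Date(ep$start %||% ep[[1]]),
       length_days = as.integer(ep$length_days %||% ep[[2]]),
       amplitude = as.numeric(ep$amplitude %||% ep[[3]]))
}

#' Default injected heat episodes: two per summer
#'
#' One short early-July episode and one longer early-August episode per
#' simulated year, warm enough to clear a 95th-percentile threshold in
#' most years but modulated by the AR(1) noise so that detected event
#' counts and durations vary.
#'
#' @param n_years,start_date as in [synth_config()].
#' @return list of episode descriptors.
#' @export
default_heat_episodes <- function(n_years, start_date = as.Date("2000-01-01")) {
  y0 <- as.integer(format(as.Date(start_date), "%Y"))
  out <- list()
  for (k in seq_len(n_years)) {
    y <- y0 + k - 1L
    out[[length(out) + 1L]] <-
      list(start = as.Date(sprintf("%d-07-05", y)), length_days = 4L,
           amplitude = 6)
    out[[length(out) + 1L]] <-
      list(start = as.Date(sprintf("%d-08-02", y)), length_days = 8L,
           amplitude = 7)
  }
  out
}

#' Generate a daily mean temperature series
#'
#' Sinusoidal annual cycle (peak near 20 July) plus AR(1) noise plus
#' additive heat-episode bumps. Deterministic for a fixed seed.
#'
#' @param config a [synth_config()] object.
#' @return data.frame (`date`, `tmean`), one row per calendar day.
#' @export
generate_temperature <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dates <- seq(config$start_date, config$end_date, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$temp_mean_annual +
    config$temp_seasonal_amplitude * cos(2 * pi * (doy - 201) / 365.25)
  noise <- numeric(n)
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    e <- rnorm(n, sd = config$noise_sd)
    phi <- config$ar1_coefficient
    # stationary start, then the AR(1) recursion
    noise[1] <- e[1] / sqrt(max(1 - phi^2, .Machine$double.eps))
    if (n > 1) for (i in 2:n) noise[i] <- phi * noise[i - 1] + e[i]
  }
  tmean <- seasonal + noise
  for (ep in config$heat_episodes) {
    i <- which(dates >= ep$start & dates < ep$start + ep$length_days)
    tmean[i] <- tmean[i] + ep$amplitude
  }
  data.frame(date = dates, tmean = tmean)
}

#' Generate stratified daily death counts with population denominators
#'
#' Draws per-stratum daily counts from a Poisson law whose log-mean is the
#' sum of a secular trend, a winter-peaked seasonal cycle, a day-of-week
#' effect, and a heat term on heat-wave days (binary log offset or
#' EHF-proportional, per the config). Populations interpolate linearly
#' between the start and end age structures, anchored at 1 July of each
#' year (mid-year population convention).
#'
#' @param config a [synth_config()] object.
#' @param temp the matching temperature series (required for the
#'   EHF-proportional heat effect; its dates define the output range).
#' @param heat_wave_days Date vector (possibly empty) of days carrying the
#'   heat effect.
#' @return data.frame (`date`, `stratum`, `deaths`, `population`) in long
#'   form, four strata per day.
#' @export
generate_mortality <- function(config, temp,
                               heat_wave_days = as.Date(character())) {
  stopifnot(inherits(config, "synth_config"))
  check_daily_temperature(temp)
  dates <- as.Date(temp$date)
  heat_wave_days <- as.Date(heat_wave_days)
  if (length(heat_wave_days) && !all(heat_wave_days %in% dates))
    stop("`heat_wave_days` must lie within the temperature date range",
         call. = FALSE)
  n <- length(dates)
  yrs_elapsed <- as.numeric(dates - dates[1]) / 365.25
  doy <- as.integer(format(dates, "%j"))
  dow <- as.integer(format(dates, "%u"))  # 1 = Monday
  hwd <- as.numeric(dates %in% heat_wave_days)

  heat_term <- if (config$heat_effect_type == "binary") {
    config$heat_effect_beta * hwd
  } else {
    thr <- compute_thresholds(temp)
    m <- compute_heat_metrics(temp, thr)
    e <- ifelse(is.na(m$ehf), 0, m$ehf)
    config$heat_effect_beta * e * hwd
  }
  log_mu_total <- log(config$base_daily_deaths) +
    log1p(config$secular_trend) * yrs_elapsed +
    config$mortality_seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    config$dow_effects[dow] + heat_term
  mu_total <- exp(log_mu_total)

  # mid-year (1 July) population shares, linear between start/end structure
  yr <- as.integer(format(dates, "%Y"))
  yr0 <- as.integer(format(config$start_date, "%Y"))
  frac <- (yr - yr0) / max(config$n_years - 1L, 1L)
  frac <- pmin(pmax(frac, 0), 1)

  set.seed(config$seed + 1L)
  out <- vector("list", length(STRATA))
  for (k in seq_along(STRATA)) {
    s <- STRATA[k]
    mu_s <- config$death_shares[[s]] * mu_total
    pop_s <- config$total_population *
      (config$age_structure_start[[s]] +
         (config$age_structure_end[[s]] - config$age_structure_start[[s]]) * frac)
    out[[k]] <- data.frame(date = dates, stratum = s,
                           deaths = rpois(n, mu_s),
                           population = pop_s)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$date, res$stratum), ]
  rownames(res) <- NULL
  res
}

#' Default standard-population weights (two age bands)
#'
#' European standard population aggregated to the 0-64 / 65+ split:
#' weights 0.89 and 0.11 over the age dimension, identical within each
#' sex.
#'
#' @return data.frame (`stratum`, `weight`); weights sum to 1 over age
#'   within each sex.
#' @export
standard_population_default <- function() {
  data.frame(stratum = STRATA,
             weight = ifelse(stratum_age(STRATA) == "65plus", 0.11, 0.89))
}

#' Write the generator's outputs as CSV
#'
#' Emits `temperature.csv` (date, tmean_c), `mortality.csv` (date,
#' stratum, deaths, population) and `standard_population.csv` (stratum,
#' weight) with ISO-8601 dates, plus the config as YAML.
#'
#' @param config a [synth_config()] object.
#' @param temp,mortality generated tables.
#' @param std_pop standard-population table.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_synth_inputs <- function(config, temp, mortality,
                               std_pop = standard_population_default(),
                               dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "temperature.csv")
  p2 <- file.path(dir, "mortality.csv")
  p3 <- file.path(dir, "standard_population.csv")
  p4 <- file.path(dir, "synth_config.yaml")
  tout <- data.frame(date = format(as.Date(temp$date)),
                     tmean_c = temp$tmean)
  write.csv(tout, p1, row.names = FALSE, quote = FALSE)
  mout <- mortality
  mout$date <- format(as.Date(mout$date))
  write.csv(mout, p2, row.names = FALSE, quote = FALSE)
  write.csv(std_pop, p3, row.names = FALSE, quote = FALSE)
  cfg <- config
  class(cfg) <- NULL
  cfg$start_date <- format(cfg$start_date)
  cfg$end_date <- format(cfg$end_date)
  cfg$heat_episodes <- lapply(cfg$heat_episodes, function(ep)
    list(start = format(ep$start), length_days = ep$length_days,
         amplitude = ep$amplitude))
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), p4)
  invisible(c(p1, p2, p3, p4))
}
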