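#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. For synthetic runs the
#' `synth` element is a [synth_config()]; for real-data runs, point
#' `temperature_csv`, `mortality_csv` and `standard_population_csv` at
#' existing files instead.
#'
#' @param synth a [synth_config()] or `NULL` for file-based input.
#' @param temperature_csv,mortality_csv,standard_population_csv input
#'   paths (ignored when `synth` is given).
#' @param p_low,p_high threshold percentiles in (0,1), `p_low < p_high`.
#' @param df_per_year spline df per year for the baseline model.
#' @param alpha two-sided level for Poisson limits and tests.
#' @param ehp_cap EHP scan cap, days.
#' @param groups population groups to analyse.
#' @param seed seed for synthetic generation (overrides `synth$seed`
#'   when non-NULL).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            temperature_csv = NULL, mortality_csv = NULL,
                            standard_population_csv = NULL,
                            p_low = 0.95, p_high = 0.98, df_per_year = 6,
                            alpha = 0.05, ehp_cap = 30L,
                            groups = c("total", "male", "female",
                                       "age0_64", "age65plus"),
                            seed = NULL) {
  if (p_low <= 0 || p_high >= 1 || p_low >= p_high)
    stop("need 0 < p_low < p_high < 1", call. = FALSE)
  if (is.null(synth)) {
    for (p in c(temperature_csv, mortality_csv, standard_population_csv))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  } else if (!is.null(seed)) {
    synth$seed <- as.integer(seed)
  }
  structure(list(synth = synth, temperature_csv = temperature_csv,
                 mortality_csv = mortality_csv,
                 standard_population_csv = standard_population_csv,
                 p_low = p_low, p_high = p_high,
                 df_per_year = df_per_year, alpha = alpha,
                 ehp_cap = as.integer(ehp_cap), groups = groups,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `synth:` block maps onto [synth_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. `seed = 42`).
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synth)) {
    sargs <- y$synth
    for (nm in c("death_shares", "age_structure_start",
                 "age_structure_end", "dow_effects"))
      if (!is.null(sargs[[nm]])) sargs[[nm]] <- unlist(sargs[[nm]])
    syn <- do.call(synth_config, sargs)
  }
  args <- y[setdiff(names(y), "synth")]
  args$synth <- syn
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

read_inputs <- function(config) {
  if (!is.null(config$synth)) {
    temp <- generate_temperature(config$synth)
    thr <- compute_thresholds(temp, config$p_low, config$p_high)
    hws0 <- detect_heat_waves(temp, thr)
    mortality <- generate_mortality(config$synth, temp,
                                    heat_wave_days(hws0))
    std_pop <- standard_population_default()
  } else {
    tr <- read.csv(config$temperature_csv)
    temp <- data.frame(date = as.Date(tr$date),
                       tmean = tr$tmean_c %||% tr$tmean)
    mortality <- read.csv(config$mortality_csv)
    mortality$date <- as.Date(mortality$date)
    std_pop <- read.csv(config$standard_population_csv)
  }
  list(temp = temp, mortality = mortality, std_pop = std_pop)
}

#' Run the full heat-wave excess-mortality pipeline
#'
#' Generates (or reads) inputs, detects heat waves and their cumulative
#' heat load, standardizes mortality, fits the baseline model per group,
#' summarizes per-event excess mortality, delimits extended heat-wave
#' periods with displacement ratios, and fits the characteristic
#' regressions. Writes all report tables as RFC-4180 CSV with ISO dates,
#' plus a JSON model summary and a run log; idempotent for a fixed
#' config.
#'
#' Events that overlap the 32-day index warm-up at the start of the
#' series are dropped (with a log entry) because their cumulative heat
#' load is undefined.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the report bundle.
#' @return invisibly, a list with every table: `temp`, `thresholds`,
#'   `heat_waves`, `rates`, `models`, `baseline`, `excess`, `ehp`,
#'   `association`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_lines <- c(sprintf("heatexcess %s | R %s.%s",
                         as.character(utils::packageVersion("heatexcess")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %s",
                         config$synth$seed %||% "(file input)"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- stage("input", read_inputs(config))
  if (!is.null(config$synth))
    write_synth_inputs(config$synth, inp$temp, inp$mortality,
                       inp$std_pop, dir = output_dir)

  thr <- stage("thresholds",
               compute_thresholds(inp$temp, config$p_low, config$p_high))
  hws <- stage("detect", detect_heat_waves(inp$temp, thr))
  # warm-up: heat load undefined in the first 32 days
  warm_end <- as.Date(inp$temp$date[1]) + 31L
  drop <- hws$start <= warm_end
  if (any(drop)) {
    log_lines <- c(log_lines,
                   sprintf("dropped %d event(s) overlapping the %s warm-up",
                           sum(drop), warm_end))
    hws <- hws[!drop, , drop = FALSE]
  }
  hws <- stage("heat load", summarize_heat_waves(hws, inp$temp, thr))
  hwd <- heat_wave_days(hws)
  log_lines <- c(log_lines, sprintf("detected %d heat wave(s), %d days",
                                    nrow(hws), length(hwd)))

  rates <- stage("standardize",
                 standardize_series(inp$mortality, inp$std_pop,
                                    config$groups))

  models <- list(); base_series <- list()
  for (g in config$groups) {
    r <- rates[rates$group == g, c("date", "rate")]
    m <- stage(paste0("baseline[", g, "]"),
               fit_baseline(r, hwd, df_per_year = config$df_per_year))
    models[[g]] <- m
    base_series[[g]] <- counterfactual_baseline(m)
  }

  exc <- stage("excess", excess_table(hws, base_series,
                                      alpha = config$alpha))

  dev_total <- base_series[["total"]] %||% base_series[[1]]
  deviations <- data.frame(date = dev_total$date,
                           rmd = daily_rmd(dev_total$observed,
                                           dev_total$baseline))
  ehp <- stage("displacement",
               delimit_ehp(hws, deviations, cap = config$ehp_cap))

  assoc <- if (nrow(hws) >= 3L) {
    stage("association", association_table(hws, exc))
  } else {
    data.frame(predictor = character(), group = character(),
               slope = numeric(), intercept = numeric(),
               r_squared = numeric(), p_value = numeric(), n = integer())
  }

  stage("write", {
    write_heatwaves_csv(hws, file.path(output_dir, "heatwaves.csv"))
    write.csv(data.frame(date = format(rates$date),
                         group = rates$group,
                         rate_per_10M = rates$rate),
              file.path(output_dir, "standardized_rates.csv"),
              row.names = FALSE, quote = FALSE)
    write_baseline_csv(base_series,
                       file.path(output_dir, "baseline.csv"))
    write_model_summary_json(models,
                             file.path(output_dir, "model_summary.json"))
    write_excess_csv(exc, hws, ehp,
                     file.path(output_dir, "excess_by_heatwave.csv"))
    write_ehp_csv(ehp, file.path(output_dir, "ehp.csv"))
    write.csv(assoc, file.path(output_dir, "association.csv"),
              row.names = FALSE, quote = FALSE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  })
  invisible(list(temp = inp$temp, thresholds = thr, heat_waves = hws,
                 rates = rates, models = models, baseline = base_series,
                 excess = exc, ehp = ehp, association = assoc,
                 heat_wave_days = hwd))
}

# report-layout writers ------------------------------------------------

write_heatwaves_csv <- function(hws, path) {
  out <- data.frame(`Heat Wave` = hws$id,
                    Start = format(as.Date(hws$start)),
                    End = format(as.Date(hws$end)),
                    Days = hws$duration_days,
                    avgTmean = round(hws$avg_tmean, 1),
                    maxTmean = round(hws$max_tmean, 1),
                    sumEHIsig = round(hws$sum_ehi_sig, 1),
                    sumEHIaccl = round(hws$sum_ehi_accl, 1),
                    sumEHF = round(hws$sum_ehf, 1),
                    check.names = FALSE)
  names(out)[7:9] <- paste0("\u2211", c("EHIsig", "EHIaccl", "EHF"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
}

write_baseline_csv <- function(base_series, path) {
  rows <- lapply(names(base_series), function(g) {
    s <- base_series[[g]]
    data.frame(date = format(s$date), group = g,
               observed = s$observed,
               fitted = s$expected_with_hw, baseline = s$baseline)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

write_model_summary_json <- function(models, path) {
  enc <- vapply(names(models), function(g) {
    m <- models[[g]]
    co <- coef(m)
    sprintf(paste0('    "%s": {"df": %d, "dispersion": %.6f, ',
                   '"hwd_coef": %.6f, "hwd_se": %s, "converged": %s, ',
                   '"intercept": %.6f}'),
            g, m$df, m$dispersion, m$hwd_coef,
            if (is.na(m$hwd_se)) "null" else sprintf("%.6f", m$hwd_se),
            if (isTRUE(m$converged)) "true" else "false",
            unname(co["(Intercept)"]))
  }, character(1))
  writeLines(c("{", paste(enc, collapse = ",\n"), "}"), path)
}

write_excess_csv <- function(exc, hws, ehp, path) {
  if (nrow(exc) == 0L) {
    writeLines(paste("id,group,excess_deaths,ci_low,ci_high,significant,",
                     "mean_rmd_pct,sum_rmd_pct,displaced_pct", sep = ""),
               path)
    return(invisible(path))
  }
  disp <- setNames(
    ifelse(ehp$absorbed, "---",
           ifelse(is.na(ehp$displaced_pct), "NA",
                  sprintf("%.1f", ehp$displaced_pct))), ehp$id)
  out <- data.frame(id = exc$id, group = exc$group,
                    excess_deaths = round(exc$excess_deaths),
                    ci_low = round(exc$ci_low),
                    ci_high = round(exc$ci_high),
                    significant = ifelse(exc$significant, "*", ""),
                    mean_rmd_pct = round(exc$mean_rmd, 1),
                    sum_rmd_pct = round(exc$sum_rmd, 1),
                    displaced_pct = unname(disp[exc$id]))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

write_ehp_csv <- function(ehp, path) {
  out <- data.frame(id = ehp$id,
                    ehp_id = ehp$ehp_id,
                    absorbed = ehp$absorbed,
                    ehp_start = ifelse(is.na(ehp$ehp_start), "---",
                                       format(ehp$ehp_start)),
                    ehp_end = ifelse(is.na(ehp$ehp_end), "---",
                                     format(ehp$ehp_end)),
                    positive_phase_end =
                      ifelse(is.na(ehp$positive_phase_end), "---",
                             format(ehp$positive_phase_end)),
                    positive_sum = round(ehp$positive_sum, 2),
                    negative_sum = round(ehp$negative_sum, 2),
                    displaced_pct = round(ehp$displaced_pct, 1),
                    degenerate = ehp$degenerate)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}
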