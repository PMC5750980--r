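#' Daily relative mortality deviation (RMD)
#'
#' Percentage deviation of observed mortality from the baseline:
#' `100 * (observed - baseline) / baseline`.
#'
#' @param observed,baseline numeric vectors of equal length; `baseline`
#'   strictly positive.
#' @return numeric vector of percentages.
#' @export
daily_rmd <- function(observed, baseline) {
  if (length(observed) != length(baseline))
    stop("`observed` and `baseline` must have equal length", call. = FALSE)
  if (any(baseline <= 0))
    stop("baseline must be strictly positive", call. = FALSE)
  100 * (observed - baseline) / baseline
}

#' Mean daily RMD from a cumulative RMD
#'
#' The per-day average relative deviation of an event is its cumulative
#' relative deviation divided by its duration — an identity the summary
#' layer uses and reports at 1-decimal precision.
#'
#' @param sum_rmd cumulative RMD over the event, percent.
#' @param duration_days event duration.
#' @param digits rounding for reporting (default 1, report precision).
#' @export
mean_rmd <- function(sum_rmd, duration_days, digits = 1) {
  round(sum_rmd / duration_days, digits)
}

#' Exact Poisson confidence limits for an excess count
#'
#' Exact (Garwood-type) limits for a Poisson-distributed observed total,
#' from the count/chi-square relation
#' `L = qchisq(alpha/2, 2 O) / 2` (0 when O = 0) and
#' `U = qchisq(1 - alpha/2, 2 (O + 1)) / 2`,
#' shifted by the expected baseline total so that the interval bounds the
#' *excess* `O - E`.
#'
#' @param observed_total non-negative observed count O.
#' @param baseline_total expected count E under the baseline.
#' @param alpha two-sided level (default 0.05).
#' @return list with `low`, `high` (bounds on the excess `O - E`),
#'   and the limit factors `l_factor = L/O`, `u_factor = U/O` (`NA` at
#'   O = 0).
#' @export
poisson_ci <- function(observed_total, baseline_total, alpha = 0.05) {
  if (observed_total < 0 || baseline_total < 0)
    stop("counts must be non-negative", call. = FALSE)
  o <- observed_total
  L <- if (o == 0) 0 else qchisq(alpha / 2, 2 * o) / 2
  U <- qchisq(1 - alpha / 2, 2 * (o + 1)) / 2
  list(low = L - baseline_total, high = U - baseline_total,
       l_factor = if (o > 0) L / o else NA_real_,
       u_factor = if (o > 0) U / o else NA_real_)
}

#' Per-heat-wave excess mortality summary
#'
#' Cumulative excess deaths (observed minus counterfactual baseline, in
#' standardized units), exact Poisson 95% limits on the excess, and the
#' cumulative and mean relative mortality deviations over the event.
#' Standardized (non-integer) totals are rounded to the nearest integer
#' for the confidence-limit computation only.
#'
#' @param hw one event (a single row of the heat-wave table, with `id`,
#'   `start`, `end`, `duration_days`).
#' @param series baseline series data.frame (`date`, `observed`,
#'   `baseline`) covering the event, from [counterfactual_baseline()].
#' @param group optional population-group label carried into the output.
#' @param alpha two-sided level for the limits.
#' @return one-row data.frame: `id`, `group`, `excess_deaths`, `ci_low`,
#'   `ci_high`, `mean_rmd`, `sum_rmd`, `significant`.
#' @export
summarize_excess <- function(hw, series, group = "total", alpha = 0.05) {
  d <- as.Date(series$date)
  i <- which(d >= as.Date(hw$start) & d <= as.Date(hw$end))
  if (length(i) != hw$duration_days)
    stop("baseline series does not cover event ", hw$id, call. = FALSE)
  obs <- series$observed[i]
  base <- series$baseline[i]
  excess <- sum(obs - base)
  rmd <- daily_rmd(obs, base)
  sum_rmd <- sum(rmd)
  ci <- poisson_ci(round(sum(obs)), sum(base), alpha = alpha)
  data.frame(id = hw$id, group = group, excess_deaths = excess,
             ci_low = ci$low, ci_high = ci$high,
             mean_rmd = sum_rmd / hw$duration_days, sum_rmd = sum_rmd,
             significant = ci$low > 0 | ci$high < 0)
}

#' Excess summaries for every event and population group
#'
#' @param hws event table from [detect_heat_waves()].
#' @param series_by_group named list of baseline series (one per group)
#'   from [counterfactual_baseline()].
#' @param alpha two-sided level.
#' @return data.frame, one row per event x group.
#' @export
excess_table <- function(hws, series_by_group, alpha = 0.05) {
  if (nrow(hws) == 0L)
    return(data.frame(id = character(), group = character(),
                      excess_deaths = numeric(), ci_low = numeric(),
                      ci_high = numeric(), mean_rmd = numeric(),
                      sum_rmd = numeric(), significant = logical()))
  rows <- lapply(names(series_by_group), function(g) {
    do.call(rbind, lapply(seq_len(nrow(hws)), function(j)
      summarize_excess(hws[j, ], series_by_group[[g]], group = g,
                       alpha = alpha)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
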