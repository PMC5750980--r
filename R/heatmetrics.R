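#' Percentile thresholds for heat-wave detection
#'
#' Computes the two temperature thresholds that define a heat wave: the
#' lower one every event day must reach, and the upper one at least one
#' event day must exceed. Both are empirical quantiles of the *annual*
#' (all-days) distribution of daily mean temperature over the reference
#' period, not a summer-only distribution.
#'
#' @param temp data.frame with columns `date` (Date) and `tmean` (deg C),
#'   gap-free daily series.
#' @param p_low,p_high probabilities in (0,1) for the lower and upper
#'   thresholds; defaults 0.95 and 0.98.
#' @param reference_period optional length-2 Date vector restricting the
#'   days that enter the quantile; default is the whole series.
#' @return An object of class `hw_thresholds`: a list with `t95`, `t98`
#'   (named after the default probabilities but holding whatever `p_low`,
#'   `p_high` request), `p_low`, `p_high`, `reference_period`, and
#'   `quantile_type` (the order-statistic interpolation rule used,
#'   `stats::quantile` type 7).
#' @examples
#' temp <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
#'                               length.out = 365),
#'                    tmean = 10 + 10 * sinpi(2 * (1:365) / 365))
#' compute_thresholds(temp)
#' @export
compute_thresholds <- function(temp, p_low = 0.95, p_high = 0.98,
                               reference_period = NULL) {
  check_daily_temperature(temp)
  if (!is.numeric(p_low) || !is.numeric(p_high) ||
      p_low <= 0 || p_low >= 1 || p_high <= 0 || p_high >= 1)
    stop("threshold probabilities must lie in (0, 1)", call. = FALSE)
  if (p_low > p_high)
    stop("`p_low` must not exceed `p_high`", call. = FALSE)
  d <- as.Date(temp$date)
  if (is.null(reference_period)) {
    reference_period <- c(min(d), max(d))
  } else {
    reference_period <- as.Date(reference_period)
  }
  keep <- d >= reference_period[1] & d <= reference_period[2]
  if (!any(keep)) stop("reference period contains no data", call. = FALSE)
  x <- temp$tmean[keep]
  if (length(x) < 365)
    warning("fewer than one year of data in the reference period; ",
            "annual-distribution quantiles may be unstable")
  q <- quantile(x, probs = c(p_low, p_high), names = FALSE, type = 7)
  structure(list(t95 = q[1], t98 = q[2], p_low = p_low, p_high = p_high,
                 reference_period = reference_period, quantile_type = 7L),
            class = "hw_thresholds")
}

#' @export
print.hw_thresholds <- function(x, ...) {
  cat(sprintf("Heat-wave thresholds (quantile type %d)\n", x$quantile_type))
  cat(sprintf("  %.0fth percentile: %.2f degC\n", 100 * x$p_low, x$t95))
  cat(sprintf("  %.0fth percentile: %.2f degC\n", 100 * x$p_high, x$t98))
  cat(sprintf("  reference period: %s to %s\n",
              x$reference_period[1], x$reference_period[2]))
  invisible(x)
}

#' Inclusive duration of a calendar-date interval
#'
#' Day count of a heat wave (or any interval) from its start and end
#' dates, both included.
#'
#' @param start,end Dates (or strings coercible to Date).
#' @return integer day count, `end - start + 1`.
#' @examples
#' heat_wave_duration("1994-07-22", "1994-08-08")  # 18
#' @export
heat_wave_duration <- function(start, end) {
  as.integer(as.Date(end) - as.Date(start)) + 1L
}

#' Detect heat waves with the two-percentile rule
#'
#' A heat wave is a maximal run of at least 3 consecutive days whose daily
#' mean temperature reaches or exceeds the lower threshold (`>= t95`),
#' provided at least one day of the run strictly exceeds the upper
#' threshold (`> t98`). Events are labelled by the calendar year of their
#' start date plus a within-year ordinal, e.g. `"1994_4"`.
#'
#' @param temp daily temperature data.frame (`date`, `tmean`).
#' @param thr an `hw_thresholds` object from [compute_thresholds()].
#' @param min_duration minimum run length in days (default 3).
#' @return data.frame with one row per event: `id`, `start`, `end`,
#'   `duration_days`. Zero rows when no run qualifies.
#' @export
detect_heat_waves <- function(temp, thr, min_duration = 3L) {
  check_daily_temperature(temp)
  if (!inherits(thr, "hw_thresholds"))
    stop("`thr` must come from compute_thresholds()", call. = FALSE)
  d <- as.Date(temp$date)
  hot <- temp$tmean >= thr$t95
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  rows <- lapply(which(keep), function(k) {
    i <- starts[k]:ends[k]
    if (!any(temp$tmean[i] > thr$t98)) return(NULL)
    data.frame(start = d[i[1]], end = d[i[length(i)]],
               duration_days = length(i))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(id = character(), start = as.Date(character()),
                      end = as.Date(character()),
                      duration_days = integer()))
  }
  out <- do.call(rbind, rows)
  yr <- format(out$start, "%Y")
  ord <- stats::ave(seq_along(yr), yr, FUN = seq_along)
  out <- cbind(id = paste(yr, ord, sep = "_"), out)
  out$id <- as.character(out$id)
  rownames(out) <- NULL
  out
}

# Backward k-day running mean; NA for days with incomplete history.
backward_mean <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))
}

#' Significance index (3-day exceedance of the heat threshold)
#'
#' Backward three-day mean temperature (days i, i-1, i-2) minus the lower
#' heat-wave threshold. Measures heat-wave intensity; defined from the
#' third day of the series.
#'
#' @param temp daily temperature data.frame (`date`, `tmean`).
#' @param thr an `hw_thresholds` object.
#' @return data.frame (`date`, `value`) with `NA` on days 1-2.
#' @export
ehi_sig <- function(temp, thr) {
  check_daily_temperature(temp)
  if (!inherits(thr, "hw_thresholds"))
    stop("`thr` must come from compute_thresholds()", call. = FALSE)
  data.frame(date = as.Date(temp$date),
             value = backward_mean(temp$tmean, 3L) - thr$t95)
}

#' Acclimatization index (3-day mean vs. the preceding 30 days)
#'
#' Backward three-day mean temperature minus the mean of the 30 days
#' preceding that window (days i-3 ... i-32). Measures departure from the
#' conditions the population recently experienced; defined from day 33.
#'
#' @param temp daily temperature data.frame (`date`, `tmean`).
#' @return data.frame (`date`, `value`) with `NA` on days 1-32.
#' @export
ehi_accl <- function(temp) {
  check_daily_temperature(temp)
  x <- temp$tmean
  n <- length(x)
  m3 <- backward_mean(x, 3L)
  s <- c(0, cumsum(x))
  m30 <- rep(NA_real_, n)
  if (n >= 33L) {
    i <- 33:n
    # mean of days i-3 .. i-32  ==  (S[i-3] - S[i-33]) / 30
    m30[i] <- (s[i - 2L] - s[i - 32L]) / 30
  }
  data.frame(date = as.Date(temp$date), value = m3 - m30)
}

#' Excess heat factor (EHF)
#'
#' Daily heat-load index combining intensity and acclimatization:
#' `max(0, ehi_sig) * max(1, ehi_accl)`. Zero whenever the three-day mean
#' does not exceed the lower threshold; never amplified downward by an
#' acclimatized population (second factor floored at 1). Undefined
#' wherever either input index is undefined.
#'
#' @param sig,accl data.frames (`date`, `value`) from [ehi_sig()] and
#'   [ehi_accl()], on identical dates.
#' @return data.frame (`date`, `value`).
#' @export
ehf <- function(sig, accl) {
  if (!identical(as.Date(sig$date), as.Date(accl$date)))
    stop("`sig` and `accl` must be on identical dates", call. = FALSE)
  data.frame(date = as.Date(sig$date),
             value = pmax(0, sig$value) * pmax(1, accl$value))
}

#' All three daily excess-heat indices at once
#'
#' @param temp daily temperature data.frame (`date`, `tmean`).
#' @param thr an `hw_thresholds` object.
#' @return data.frame (`date`, `ehi_sig`, `ehi_accl`, `ehf`).
#' @export
compute_heat_metrics <- function(temp, thr) {
  sig <- ehi_sig(temp, thr)
  accl <- ehi_accl(temp)
  data.frame(date = sig$date, ehi_sig = sig$value, ehi_accl = accl$value,
             ehf = ehf(sig, accl)$value)
}

#' Per-event temperature and cumulative heat-load summaries
#'
#' For each detected heat wave: average and maximum daily mean
#' temperature, and the raw sums of the three daily indices over the event
#' days (the event's total heat load). Daily significance-index values
#' enter the sum signed; the EHF is already floored at zero daily.
#'
#' @param hws event data.frame from [detect_heat_waves()].
#' @param temp daily temperature data.frame.
#' @param thr an `hw_thresholds` object.
#' @return `hws` with columns `avg_tmean`, `max_tmean`, `sum_ehi_sig`,
#'   `sum_ehi_accl`, `sum_ehf` appended.
#' @export
summarize_heat_waves <- function(hws, temp, thr) {
  check_daily_temperature(temp)
  metrics <- compute_heat_metrics(temp, thr)
  d <- as.Date(temp$date)
  cols <- c("avg_tmean", "max_tmean", "sum_ehi_sig", "sum_ehi_accl",
            "sum_ehf")
  if (nrow(hws) == 0L) {
    for (cl in cols) hws[[cl]] <- numeric(0)
    return(hws)
  }
  out <- lapply(seq_len(nrow(hws)), function(j) {
    i <- which(d >= hws$start[j] & d <= hws$end[j])
    if (length(i) != hws$duration_days[j])
      stop("temperature series does not cover event ", hws$id[j],
           call. = FALSE)
    if (anyNA(metrics$ehf[i]))
      stop("event ", hws$id[j], " overlaps the 32-day index warm-up; ",
           "cumulative heat load is undefined there", call. = FALSE)
    c(avg_tmean = mean(temp$tmean[i]), max_tmean = max(temp$tmean[i]),
      sum_ehi_sig = sum(metrics$ehi_sig[i]),
      sum_ehi_accl = sum(metrics$ehi_accl[i]),
      sum_ehf = sum(metrics$ehf[i]))
  })
  cbind(hws, do.call(rbind, out))
}

#' Dates covered by a set of heat waves
#'
#' @param hws event data.frame (`start`, `end` columns).
#' @return Date vector of all event days (sorted, unique).
#' @export
heat_wave_days <- function(hws) {
  if (nrow(hws) == 0L) return(as.Date(character()))
  out <- unlist(lapply(seq_len(nrow(hws)), function(j)
    seq(as.Date(hws$start[j]), as.Date(hws$end[j]), by = "day")))
  sort(unique(as.Date(out, origin = "1970-01-01")))
}
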