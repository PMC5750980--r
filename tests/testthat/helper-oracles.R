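# Independent oracles used across the suite. These deliberately use naive
# loops / numerical inversion, not the package's vectorized paths.

# thresholds object with hand-set cutoffs (bypasses quantile estimation)
manual_thresholds <- function(t95, t98) {
  structure(list(t95 = t95, t98 = t98, p_low = 0.95, p_high = 0.98,
                 reference_period = NULL, quantile_type = 7L),
            class = "hw_thresholds")
}

temp_series <- function(tmean, start = as.Date("2000-01-01")) {
  data.frame(date = seq(start, by = "day", length.out = length(tmean)),
             tmean = tmean)
}

# sort-and-interpolate quantile oracle (type-7 definition, written out)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force run-scan detector: walk every day, grow runs by loop
detect_oracle <- function(tmean, t95, t98, min_len = 3L) {
  n <- length(tmean)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (tmean[i] >= t95) {
      j <- i
      while (j < n && tmean[j + 1L] >= t95) j <- j + 1L
      if (j - i + 1L >= min_len) {
        peak <- FALSE
        for (k in i:j) if (tmean[k] > t98) peak <- TRUE
        if (peak) events[[length(events) + 1L]] <- c(i, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  events
}

# naive per-day loops for the three excess-heat indices
ehi_sig_oracle <- function(tmean, t95) {
  n <- length(tmean)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= 3) out[i] <- (tmean[i] + tmean[i - 1] + tmean[i - 2]) / 3 - t95
  }
  out
}

ehi_accl_oracle <- function(tmean) {
  n <- length(tmean)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= 33) {
      m3 <- (tmean[i] + tmean[i - 1] + tmean[i - 2]) / 3
      m30 <- mean(tmean[(i - 32):(i - 3)])
      out[i] <- m3 - m30
    }
  }
  out
}

ehf_oracle <- function(sig, accl) {
  n <- length(sig)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(sig[i]) && !is.na(accl[i]))
      out[i] <- max(0, sig[i]) * max(1, accl[i])
  }
  out
}

# exact Poisson limits by numerical inversion of the tail sums
poisson_limits_oracle <- function(o, alpha = 0.05) {
  lower <- if (o == 0) 0 else
    uniroot(function(l) 1 - ppois(o - 1, l) - alpha / 2,
            c(1e-10, o + 1), tol = 1e-12)$root
  upper <- uniroot(function(u) ppois(o, u) - alpha / 2,
                   c(o + 1e-10, 5 * o + 50), tol = 1e-12)$root
  c(lower, upper)
}

# window-enumeration oracle for EHP phases: classify every 3-day window
# by the sign of its centered average, then read off phase bounds
ehp_oracle <- function(x, ev_start, ev_end) {
  n <- length(x)
  s <- rep(NA_real_, n)
  for (d in 2:(n - 1)) s[d] <- mean(x[(d - 1):(d + 1)])
  start <- ev_start
  while (start > 2 && !is.na(s[start - 1]) && s[start - 1] > 0)
    start <- start - 1
  if (is.na(s[ev_start]) || s[ev_start] <= 0) start <- ev_start
  pos_end <- ev_end
  while (pos_end < n - 1 && s[pos_end + 1] > 0) pos_end <- pos_end + 1
  neg_end <- pos_end
  while (neg_end < n - 1 && s[neg_end + 1] < 0) neg_end <- neg_end + 1
  list(start = start, pos_end = pos_end, neg_end = neg_end,
       pos_sum = sum(s[start:pos_end]),
       neg_sum = if (neg_end > pos_end)
         sum(s[(pos_end + 1):neg_end]) else 0)
}

dev_series <- function(rmd, start = as.Date("2000-06-01")) {
  data.frame(date = seq(start, by = "day", length.out = length(rmd)),
             rmd = rmd)
}

one_event <- function(start, end, id = "2000_1") {
  data.frame(id = id, start = as.Date(start), end = as.Date(end),
             duration_days = heat_wave_duration(start, end))
}

# small helper: total daily deaths from the long stratified table
total_deaths_series <- function(mortality) {
  agg <- aggregate(deaths ~ date, data = mortality, FUN = sum)
  agg <- agg[order(agg$date), ]
  data.frame(date = as.Date(agg$date), rate = agg$deaths)
}
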