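test_that("thresholds are empirical annual-distribution quantiles", {
  # constant series: every quantile equals the constant
  temp <- temp_series(rep(20, 365))
  thr <- compute_thresholds(temp)
  expect_equal(thr$t95, 20)
  expect_equal(thr$t98, 20)

  # values 1..100, one each: matches the sort-and-interpolate oracle
  temp <- suppressWarnings(compute_thresholds(temp_series(1:100)))
  expect_equal(temp$t95, quantile_oracle(1:100, 0.95))
  expect_equal(temp$t98, quantile_oracle(1:100, 0.98))

  # and on arbitrary values
  set.seed(11)
  x <- rnorm(800, 10, 6)
  thr <- compute_thresholds(temp_series(x))
  expect_equal(thr$t95, quantile_oracle(x, 0.95), tolerance = 1e-12)
  expect_equal(thr$t98, quantile_oracle(x, 0.98), tolerance = 1e-12)

  expect_error(compute_thresholds(temp_series(1:400), p_low = 0.98,
                                  p_high = 0.95), "p_low")
  expect_error(compute_thresholds(data.frame(date = as.Date(character()),
                                             tmean = numeric())), "empty")
})

test_that("detector keeps >=3-day runs at t95 with a day above t98", {
  # runs of length 2, length 3 (with a peak), and length 5 (peak-free)
  tmean <- c(rep(10, 5), 21, 22, rep(10, 4), 21, 24, 21, rep(10, 4),
             rep(22, 5), rep(10, 5))
  thr <- manual_thresholds(21, 23)
  hws <- detect_heat_waves(temp_series(tmean), thr)
  expect_equal(nrow(hws), 1L)
  expect_equal(hws$duration_days, 3L)
  expect_equal(as.integer(hws$start - as.Date("2000-01-01")) + 1L, 12L)

  # boundary semantics: reaching t95 counts, merely reaching t98 does not
  expect_equal(nrow(detect_heat_waves(temp_series(rep(21, 10)),
                                      manual_thresholds(21, 23))), 0L)
  expect_equal(nrow(detect_heat_waves(temp_series(rep(23, 10)),
                                      manual_thresholds(21, 23))), 0L)
  hws2 <- detect_heat_waves(temp_series(rep(23.5, 10)),
                            manual_thresholds(21, 23))
  expect_equal(hws2$duration_days, 10L)

  # never reaching t95: empty result
  expect_equal(nrow(detect_heat_waves(temp_series(rep(5, 400)),
                                      manual_thresholds(21, 23))), 0L)
})

test_that("detector ids carry start-year and within-year ordinal", {
  tmean <- rep(10, 800)
  tmean[360:370] <- 25   # wave crossing into late December
  tmean[500:504] <- 25
  tmean[600:604] <- 25
  hws <- detect_heat_waves(temp_series(tmean), manual_thresholds(20, 22))
  expect_equal(hws$id, c("2000_1", "2001_1", "2001_2"))
})

test_that("a qualifying 3-15 August window has duration 13", {
  d0 <- as.Date("2015-06-01")
  n <- 150
  tmean <- rep(15, n)
  i <- which(seq(d0, by = "day", length.out = n) >=
               as.Date("2015-08-03") &
             seq(d0, by = "day", length.out = n) <= as.Date("2015-08-15"))
  tmean[i] <- 26
  hws <- detect_heat_waves(temp_series(tmean, start = d0),
                           manual_thresholds(21.2, 23.2))
  expect_equal(nrow(hws), 1L)
  expect_equal(hws$duration_days, 13L)
  expect_equal(heat_wave_duration(hws$start, hws$end), 13L)
})

test_that("excess-heat indices match naive loop oracles", {
  # forced arithmetic: T = (20, 22, 24), t95 = 21.2 -> day-3 value 0.8
  thr <- manual_thresholds(21.2, 23.2)
  s <- ehi_sig(temp_series(c(20, 22, 24)), thr)
  expect_true(all(is.na(s$value[1:2])))
  expect_equal(s$value[3], 0.8)

  # constant series: sig == c - t95 everywhere defined, accl == 0
  tempc <- temp_series(rep(25, 60))
  expect_equal(unique(ehi_sig(tempc, thr)$value[-(1:2)]), 25 - 21.2)
  expect_equal(unique(ehi_accl(tempc)$value[-(1:32)]), 0)

  # 30 days at 10 then 3 days at 16: acclimatization index 6 on day 33
  a <- ehi_accl(temp_series(c(rep(10, 30), rep(16, 3))))
  expect_equal(a$value[33], 6)

  # elementwise agreement with the loop oracles on random series
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(120, 15, 6)
    temp <- temp_series(x)
    expect_equal(ehi_sig(temp, thr)$value, ehi_sig_oracle(x, 21.2),
                 tolerance = 1e-12)
    expect_equal(ehi_accl(temp)$value, ehi_accl_oracle(x),
                 tolerance = 1e-12)
    sig <- ehi_sig(temp, thr); accl <- ehi_accl(temp)
    expect_equal(ehf(sig, accl)$value,
                 ehf_oracle(sig$value, accl$value), tolerance = 1e-12)
  }
})

test_that("EHF floors both factors and rejects misaligned dates", {
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 3)
  mk <- function(v) data.frame(date = d, value = v)
  out <- ehf(mk(c(-0.5, 2.0, 3)), mk(c(5, 0.5, 2)))$value
  expect_equal(out, c(0, 2.0, 6))
  expect_error(ehf(mk(1:3), data.frame(date = d + 1, value = 1:3)),
               "identical dates")
})

test_that("event summaries sum raw daily indices over event days", {
  # 3-day event on a constant series at t95 + 1: sum_ehi_sig = 3
  thr <- manual_thresholds(21, 22.5)
  tmean <- c(rep(15, 40), rep(23, 3), rep(15, 10))
  temp <- temp_series(tmean)
  hws <- detect_heat_waves(temp, thr)
  out <- summarize_heat_waves(hws, temp, thr)
  # first two event days have a mixed 3-day window; third is (23,23,23)
  expect_equal(out$sum_ehi_sig,
               sum(ehi_sig_oracle(tmean, 21)[41:43]), tolerance = 1e-12)
  expect_equal(out$avg_tmean, 23)
  expect_equal(out$max_tmean, 23)

  # random event: sums match the loop oracles
  set.seed(31)
  x <- c(rnorm(50, 15, 2), rnorm(5, 26, 0.5), rnorm(20, 15, 2))
  temp <- temp_series(x)
  thr2 <- manual_thresholds(20, 22)
  hws2 <- detect_heat_waves(temp, thr2)
  out2 <- summarize_heat_waves(hws2, temp, thr2)
  for (j in seq_len(nrow(out2))) {
    i <- which(temp$date >= out2$start[j] & temp$date <= out2$end[j])
    expect_equal(out2$sum_ehi_sig[j], sum(ehi_sig_oracle(x, 20)[i]),
                 tolerance = 1e-12)
    expect_equal(out2$sum_ehi_accl[j], sum(ehi_accl_oracle(x)[i]),
                 tolerance = 1e-12)
    expect_equal(out2$sum_ehf[j],
                 sum(ehf_oracle(ehi_sig_oracle(x, 20),
                                ehi_accl_oracle(x))[i]),
                 tolerance = 1e-12)
  }

  # events inside the 32-day warm-up are rejected, not silently summed
  xw <- c(rep(25, 5), rep(10, 60))
  thrw <- manual_thresholds(20, 22)
  hww <- detect_heat_waves(temp_series(xw), thrw)
  expect_error(summarize_heat_waves(hww, temp_series(xw), thrw),
               "warm-up")
})

test_that("index invariances: level shift and event warming", {
  set.seed(41)
  x <- rnorm(400, 12, 7)
  temp <- temp_series(x)
  thr <- compute_thresholds(temp)
  shifted <- temp_series(x + 3.5)
  thr2 <- compute_thresholds(shifted)
  # +c degC shifts both thresholds by +c and leaves acclimatization alone
  expect_equal(thr2$t95, thr$t95 + 3.5, tolerance = 1e-12)
  expect_equal(thr2$t98, thr$t98 + 3.5, tolerance = 1e-12)
  expect_equal(ehi_accl(shifted)$value, ehi_accl(temp)$value,
               tolerance = 1e-12)

  # EHF is zero whenever the 3-day mean is at or below t95
  m <- compute_heat_metrics(temp, thr)
  def <- !is.na(m$ehf)
  expect_true(all(m$ehf[def] >= 0))
  expect_true(all(m$ehf[def & m$ehi_sig <= 0] == 0))
  expect_true(all(m$ehf[def] >= pmax(0, m$ehi_sig[def]) - 1e-12))

  # warming every day of a detected event strictly increases its sum_ehf
  hws <- detect_heat_waves(temp, thr)
  hws <- hws[as.Date(hws$start) > temp$date[1] + 32, , drop = FALSE]
  if (nrow(hws) > 0) {
    j <- 1L
    i <- which(temp$date >= hws$start[j] & temp$date <= hws$end[j])
    warmed <- temp
    warmed$tmean[i] <- warmed$tmean[i] + 1
    before <- summarize_heat_waves(hws[j, ], temp, thr)$sum_ehf
    after <- summarize_heat_waves(hws[j, ], warmed, thr)$sum_ehf
    expect_gt(after, before)
  }
})

test_that("detector agrees with the brute-force oracle on random series", {
  set.seed(51)
  for (rep in 1:50) {
    x <- 15 + cumsum(rnorm(400, 0, 1.5))
    temp <- temp_series(x)
    thr <- compute_thresholds(temp)
    hws <- detect_heat_waves(temp, thr)
    oracle <- detect_oracle(x, thr$t95, thr$t98)
    expect_equal(nrow(hws), length(oracle))
    if (length(oracle)) {
      oracle_start <- temp$date[vapply(oracle, `[`, numeric(1), 1)]
      oracle_end <- temp$date[vapply(oracle, `[`, numeric(1), 2)]
      expect_equal(as.Date(hws$start), as.Date(oracle_start))
      expect_equal(as.Date(hws$end), as.Date(oracle_end))
    }
  }
})
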