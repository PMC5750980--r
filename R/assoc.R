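#' Regress cumulative excess mortality on a heat-wave characteristic
#'
#' Ordinary least squares of the per-event cumulative relative mortality
#' deviation on one heat-wave characteristic (cumulative heat-load index,
#' temperature summary, or duration), with R-squared, the two-sided slope
#' p-value, and a pointwise 95% confidence band for the fitted line.
#'
#' @param events data.frame with one row per event containing the
#'   predictor column and a `sum_rmd` response column (join of the
#'   heat-wave and excess tables for one population group).
#' @param predictor one of `"sum_ehf"`, `"sum_ehi_sig"`,
#'   `"sum_ehi_accl"`, `"avg_tmean"`, `"max_tmean"`, `"duration_days"`
#'   (any numeric column of `events`).
#' @param group population-group label carried into the output.
#' @param response response column (default `"sum_rmd"`).
#' @return object of class `hw_association`: list with `predictor`,
#'   `group`, `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `ci_band` (data.frame `x`, `fit`, `lwr`, `upr`), and the `lm` fit.
#' @export
fit_association <- function(events, predictor, group = "total",
                            response = "sum_rmd") {
  stopifnot(predictor %in% names(events), response %in% names(events))
  x <- events[[predictor]]
  y <- events[[response]]
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " event(s) with undefined ", predictor,
            " excluded listwise")
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 events with defined predictor", call. = FALSE)
  if (max(x) - min(x) < .Machine$double.eps^0.5 * max(abs(x), 1))
    stop("constant predictor: ", predictor, call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 50))
  band <- as.data.frame(predict(fit, newdata = grid,
                                interval = "confidence", level = 0.95))
  structure(list(predictor = predictor, group = group,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x), n_dropped = dropped,
                 ci_band = cbind(grid, band), fit = fit),
            class = "hw_association")
}

#' @export
print.hw_association <- function(x, ...) {
  cat(sprintf(
    "sum_rmd ~ %s (%s): slope %.3g, R^2 = %.2f, p = %.3g (n = %d)\n",
    x$predictor, x$group, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
plot.hw_association <- function(x, ...) {
  mf <- x$fit$model
  plot(mf$x, mf$y, pch = 16, xlab = x$predictor,
       ylab = "cumulative RMD (%)",
       main = sprintf("%s, R^2 = %.2f", x$group, x$r_squared), ...)
  graphics::abline(x$fit)
  graphics::lines(x$ci_band$x, x$ci_band$lwr, lty = 3)
  graphics::lines(x$ci_band$x, x$ci_band$upr, lty = 3)
  invisible(x)
}

#' Association table over predictors and population groups
#'
#' @param hws summarized heat-wave table (with heat-load columns).
#' @param excess excess table from [excess_table()].
#' @param predictors characteristics to regress on.
#' @param groups population groups to include.
#' @return data.frame (`predictor`, `group`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`).
#' @export
association_table <- function(hws, excess,
                              predictors = c("sum_ehf", "sum_ehi_sig",
                                             "sum_ehi_accl", "avg_tmean",
                                             "max_tmean",
                                             "duration_days"),
                              groups = unique(excess$group)) {
  rows <- list()
  for (g in groups) {
    ev <- merge(hws, excess[excess$group == g, ], by = "id")
    for (p in predictors) {
      a <- fit_association(ev, p, group = g)
      rows[[length(rows) + 1L]] <-
        data.frame(predictor = p, group = g, slope = a$slope,
                   intercept = a$intercept, r_squared = a$r_squared,
                   p_value = a$p_value, n = a$n)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Compare per-event mean relative deviations between two groups
#'
#' Welch two-sample t-test on the per-event mean RMDs of two population
#' groups (e.g. men vs. women, younger vs. elderly).
#'
#' @param rmd_a,rmd_b numeric vectors of per-event mean RMDs.
#' @param alpha decision level (default 0.05).
#' @return list: `statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `significant`, `degenerate` (TRUE when either group has ~zero
#'   variance, in which case the Welch statistic is unreliable).
#' @export
compare_groups <- function(rmd_a, rmd_b, alpha = 0.05) {
  if (length(rmd_a) < 2L || length(rmd_b) < 2L)
    stop("need at least 2 events per group", call. = FALSE)
  degenerate <- stats::var(rmd_a) < 1e-12 && stats::var(rmd_b) < 1e-12
  if (degenerate) {
    return(list(statistic = NA_real_,
                p_value = if (isTRUE(all.equal(mean(rmd_a), mean(rmd_b))))
                  1 else NA_real_,
                mean_a = mean(rmd_a), mean_b = mean(rmd_b),
                significant = FALSE, degenerate = TRUE))
  }
  tt <- t.test(rmd_a, rmd_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(rmd_a), mean_b = mean(rmd_b),
       significant = tt$p.value < alpha, degenerate = FALSE)
}
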