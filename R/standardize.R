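#' Directly standardized death rate for one day
#'
#' Weights stratum-specific death rates by a fixed standard population:
#' `sum_a (deaths_a / population_a) * weight_a * 1e7`, i.e. deaths per
#' 10,000,000 standard population.
#'
#' @param deaths,populations named numeric vectors over the same strata.
#' @param weights named standard-population weights over those strata
#'   (renormalized to sum 1 internally, so subsetting to a group is safe).
#' @return scalar standardized rate per 10,000,000.
#' @export
standardized_rate <- function(deaths, populations, weights) {
  strata <- names(weights)
  if (is.null(strata) || is.null(names(deaths)) || is.null(names(populations)))
    stop("`deaths`, `populations` and `weights` must be named by stratum",
         call. = FALSE)
  missing <- setdiff(strata, intersect(names(deaths), names(populations)))
  if (length(missing))
    stop("stratum missing from inputs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  deaths <- deaths[strata]; populations <- populations[strata]
  if (any(populations <= 0))
    stop("populations must be strictly positive", call. = FALSE)
  if (any(deaths < 0)) stop("deaths must be non-negative", call. = FALSE)
  w <- weights / sum(weights)
  sum(deaths / populations * w) * 1e7
}

# group -> which strata it pools; sex groups standardize over age within
# sex, age groups pool the sexes (sex is never standardized over)
group_strata <- function(group) {
  switch(group,
    total = STRATA,
    male = STRATA[stratum_sex(STRATA) == "male"],
    female = STRATA[stratum_sex(STRATA) == "female"],
    age0_64 = STRATA[stratum_age(STRATA) == "0_64"],
    age65plus = STRATA[stratum_age(STRATA) == "65plus"],
    stop("unknown population group: ", group, call. = FALSE))
}

#' Age-standardized daily rate series per population group
#'
#' Builds one directly standardized series per requested group. Within a
#' group, strata sharing an age band are pooled (deaths and populations
#' summed) and age bands are weighted by the renormalized standard
#' weights; sex-specific series therefore standardize over age within
#' sex, and age-band series reduce to crude pooled rates.
#'
#' @param mortality long data.frame (`date`, `stratum`, `deaths`,
#'   `population`).
#' @param std_pop data.frame (`stratum`, `weight`).
#' @param groups subset of `c("total", "male", "female", "age0_64",
#'   "age65plus")`.
#' @return data.frame (`date`, `group`, `rate`), rate per 10,000,000.
#' @export
standardize_series <- function(mortality, std_pop,
                               groups = c("total", "male", "female",
                                          "age0_64", "age65plus")) {
  stopifnot(all(c("date", "stratum", "deaths", "population") %in%
                  names(mortality)))
  if (any(mortality$deaths < 0))
    stop("deaths must be non-negative", call. = FALSE)
  if (any(mortality$population <= 0))
    stop("populations must be strictly positive", call. = FALSE)
  w_all <- setNames(std_pop$weight, std_pop$stratum)
  dates <- sort(unique(as.Date(mortality$date)))
  mortality$date <- as.Date(mortality$date)

  out <- lapply(groups, function(g) {
    strata <- group_strata(g)
    if (!all(strata %in% mortality$stratum))
      stop("stratum missing from mortality table for group ", g,
           call. = FALSE)
    if (!all(strata %in% names(w_all)))
      stop("stratum missing from standard population for group ", g,
           call. = FALSE)
    sub <- mortality[mortality$stratum %in% strata, ]
    # pool sexes within an age band, then weight age bands
    band <- stratum_age(sub$stratum)
    key <- interaction(format(sub$date), band, drop = TRUE)
    deaths <- tapply(sub$deaths, key, sum)
    pops <- tapply(sub$population, key, sum)
    bands <- unique(stratum_age(strata))
    wb <- vapply(bands, function(b)
      sum(w_all[strata[stratum_age(strata) == b]]), numeric(1))
    wb <- wb / sum(wb)
    rate <- vapply(format(dates), function(dd) {
      nm <- paste(dd, bands, sep = ".")
      sum(deaths[nm] / pops[nm] * wb) * 1e7
    }, numeric(1))
    data.frame(date = dates, group = g, rate = as.numeric(rate))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
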