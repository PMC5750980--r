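# Internal validators shared across modules.

# A daily temperature series: data.frame(date = Date, tmean = numeric),
# strictly increasing gap-free dates, finite values.
check_daily_temperature <- function(temp) {
  if (!is.data.frame(temp) || !all(c("date", "tmean") %in% names(temp)))
    stop("`temp` must be a data.frame with columns `date` and `tmean`",
         call. = FALSE)
  if (nrow(temp) == 0L) stop("empty temperature series", call. = FALSE)
  d <- as.Date(temp$date)
  if (anyNA(d)) stop("unparseable dates in temperature series", call. = FALSE)
  dd <- diff(as.integer(d))
  if (length(dd) && any(dd != 1L))
    stop("temperature dates must be strictly increasing and gap-free",
         call. = FALSE)
  if (any(!is.finite(temp$tmean)))
    stop("non-finite daily mean temperatures", call. = FALSE)
  invisible(temp)
}

check_date_series <- function(date) {
  d <- as.Date(date)
  dd <- diff(as.integer(d))
  if (length(dd) && any(dd != 1L))
    stop("dates must be strictly increasing and gap-free", call. = FALSE)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
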