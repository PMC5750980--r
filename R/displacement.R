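#' Three-day centered moving average
#'
#' @param x numeric vector (length >= 3).
#' @return vector of the same length; `NA` at both ends where the
#'   centered window is incomplete.
#' @export
moving_average_3 <- function(x) {
  if (length(x) < 3L) stop("need at least 3 days", call. = FALSE)
  as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
}

#' Delimit extended heat-wave periods and the displacement ratio
#'
#' Around each heat wave an "extended heat-wave period" (EHP) is carved
#' out of the 3-day centered moving average of daily mortality
#' deviations: walking backward from the event start while the smoothed
#' deviation stays positive fixes the EHP start; walking forward from the
#' event end, the positive phase ends at the last day of the contiguous
#' positive run, and the negative phase then extends while the smoothed
#' deviation stays negative, fixing the EHP end. A smoothed value of
#' exactly zero terminates a phase. Consecutive events with no drop of
#' the smoothed deviation to or below zero between them merge into a
#' single EHP (the earlier events are marked `absorbed`). Scans are
#' capped at `cap` days from the event.
#'
#' Displaced mortality (short-term displacement, "harvesting") is
#' `100 * |negative-phase sum| / positive-phase sum` of the smoothed
#' deviations.
#'
#' @param hws event table (`id`, `start`, `end`, `duration_days`),
#'   sorted by start.
#' @param deviations data.frame (`date`, `rmd`) of daily relative
#'   mortality deviations (%) on a gap-free date grid covering the
#'   events.
#' @param cap maximum scan length, days (default 30).
#' @return data.frame with one row per event: `id`, `absorbed` (event
#'   merged into the following EHP), `ehp_id` (id of the last event in
#'   its EHP), `ehp_start`, `ehp_end`, `positive_phase_end`,
#'   `positive_sum`, `negative_sum`, `displaced_pct`, `degenerate`
#'   (no positive smoothed deviation at the event start). Phase columns
#'   are `NA` on absorbed rows.
#' @export
delimit_ehp <- function(hws, deviations, cap = 30L) {
  d <- check_date_series(deviations$date)
  s <- moving_average_3(deviations$rmd)
  n <- length(d)
  if (nrow(hws) == 0L)
    return(data.frame(id = character(), absorbed = logical(),
                      ehp_id = character(),
                      ehp_start = as.Date(character()),
                      ehp_end = as.Date(character()),
                      positive_phase_end = as.Date(character()),
                      positive_sum = numeric(), negative_sum = numeric(),
                      displaced_pct = numeric(), degenerate = logical()))
  hws <- hws[order(as.Date(hws$start)), ]
  idx <- function(day) match(as.Date(day), d)
  pos <- function(i) !is.na(s[i]) && s[i] > 0
  neg <- function(i) !is.na(s[i]) && s[i] < 0

  nev <- nrow(hws)
  out <- data.frame(id = hws$id, absorbed = FALSE, ehp_id = hws$id,
                    ehp_start = as.Date(NA), ehp_end = as.Date(NA),
                    positive_phase_end = as.Date(NA),
                    positive_sum = NA_real_, negative_sum = NA_real_,
                    displaced_pct = NA_real_, degenerate = FALSE)
  j <- 1L
  while (j <= nev) {
    members <- j
    i_start <- idx(hws$start[j])
    i_end <- idx(hws$end[j])
    if (is.na(i_start) || is.na(i_end))
      stop("deviation series does not cover event ", hws$id[j],
           call. = FALSE)
    # backward scan for the EHP start
    degenerate <- !pos(i_start)
    i0 <- i_start
    if (!degenerate) {
      lim <- max(1L, i_start - cap)
      while (i0 > lim && pos(i0 - 1L)) i0 <- i0 - 1L
    }
    # forward scan: extend the positive phase, merging events whose
    # separating days never drop to or below zero
    i_pos_end <- i_end
    repeat {
      lim <- min(n, i_end + cap)
      k <- i_end
      while (k < lim && pos(k + 1L)) k <- k + 1L
      i_pos_end <- k
      nxt <- members[length(members)] + 1L
      if (nxt <= nev && i_pos_end >= idx(hws$start[nxt]) - 1L &&
          idx(hws$start[nxt]) - 1L <= lim) {
        members <- c(members, nxt)
        i_end <- idx(hws$end[nxt])
        i_pos_end <- max(i_pos_end, i_end)
        next
      }
      break
    }
    # negative phase
    i1 <- i_pos_end
    lim <- min(n, i_pos_end + cap)
    while (i1 < lim && neg(i1 + 1L)) i1 <- i1 + 1L
    last <- members[length(members)]
    pos_days <- i0:i_pos_end
    neg_days <- if (i1 > i_pos_end) (i_pos_end + 1L):i1 else integer(0)
    positive_sum <- sum(s[pos_days], na.rm = TRUE)
    negative_sum <- if (length(neg_days)) sum(s[neg_days]) else 0
    displaced <- if (positive_sum > 0)
      100 * abs(negative_sum) / positive_sum else NA_real_
    out$absorbed[members] <- c(rep(TRUE, length(members) - 1L), FALSE)
    out$ehp_id[members] <- hws$id[last]
    out$ehp_start[last] <- d[i0]
    out$ehp_end[last] <- d[max(i1, i_pos_end)]
    out$positive_phase_end[last] <- d[i_pos_end]
    out$positive_sum[last] <- positive_sum
    out$negative_sum[last] <- negative_sum
    out$displaced_pct[last] <- displaced
    out$degenerate[last] <- degenerate
    j <- last + 1L
  }
  rownames(out) <- NULL
  out
}

#' Displacement ratio of an extended heat-wave period
#'
#' `100 * |negative_sum| / positive_sum`; undefined (NA, with a warning)
#' when the positive-phase sum is not positive.
#'
#' @param positive_sum,negative_sum phase sums of the 3-day-averaged
#'   deviations.
#' @export
displacement_ratio <- function(positive_sum, negative_sum) {
  if (positive_sum <= 0) {
    warning("non-positive positive-phase sum; displacement undefined")
    return(NA_real_)
  }
  100 * abs(negative_sum) / positive_sum
}
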