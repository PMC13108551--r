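.PERIODS <- c("laying", "incubation", "hatching", "nestling", "fledging")

#' Annual mean temperature over a fixed calendar window
#'
#' Arithmetic mean of the daily temperatures inside the closed month-day
#' window (default 15 February to 5 June, the breeding-season window: the
#' laying-cue onset through the average end of breeding) for each year,
#' with the SE of the daily values attached. Years missing more than
#' `max_missing` of the window's days are flagged; years with no days at
#' all are absent.
#'
#' @param series A [daily_temps] series.
#' @param start,end Month-day anchors `"MM-DD"` (closed interval).
#' @param max_missing Highest tolerated fraction of missing days before a
#'   year is flagged (default 0.1).
#' @return An `annual_series` data frame: `year`, `value`, `se`, `n_days`,
#'   `n_missing`, `flagged`.
#' @export
fixed_interval_annual_means <- function(series, start = "02-15",
                                        end = "06-05", max_missing = 0.1) {
  m <- temp_matrix(series)
  doys <- md_to_doy(start):md_to_doy(end)
  sub <- m[, doys, drop = FALSE]
  n_days <- rowSums(!is.na(sub))
  keep <- n_days > 0L
  sub <- sub[keep, , drop = FALSE]
  value <- rowMeans(sub, na.rm = TRUE)
  se <- apply(sub, 1L, function(v) stats::sd(v, na.rm = TRUE)) /
    sqrt(n_days[keep])
  out <- data.frame(year = as.integer(rownames(m))[keep],
                    value = value,
                    se = se,
                    n_days = n_days[keep],
                    n_missing = length(doys) - n_days[keep],
                    flagged = (length(doys) - n_days[keep]) >
                      max_missing * length(doys))
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Reproductive-period bounds for one breeding attempt
#'
#' The five biologically anchored windows, as closed April-day intervals:
#' egg laying runs from the first egg to the day before incubation starts
#' (one egg per day, so `laying + clutch - 1` is used when the incubation
#' start is unrecorded); incubation runs to the day before hatching (so
#' hatching day is counted once); hatching is hatch day to 7 days
#' post-hatch; nestling 8 to 15; fledging 16 to 21 days post-hatch.
#' Periods whose inputs are unobserved are `NULL`.
#'
#' @param attempt One row of a `breeding_attempts` table (or any list with
#'   the same fields).
#' @return A `reproductive_periods` list of `c(start, end)` April-day pairs
#'   (or `NULL`), named by period.
#' @export
relative_period_bounds <- function(attempt) {
  lay <- attempt$laying_april_day
  if (is.null(lay) || is.na(lay)) stop("laying date absent")
  inc <- attempt$incubation_start_april_day
  hatch <- attempt$hatch_april_day
  if (is.null(inc)) inc <- NA_integer_
  if (is.null(hatch)) hatch <- NA_integer_
  if (is.na(inc)) inc <- lay + attempt$clutch_size  # egg-a-day fallback
  if (!is.na(hatch) && hatch < inc)
    stop("hatch date before incubation start in attempt ",
         attempt$attempt_id)
  per <- list(
    laying = c(lay, inc - 1L),
    incubation = if (!is.na(hatch)) c(inc, hatch - 1L),
    hatching = if (!is.na(hatch)) c(hatch, hatch + 7L),
    nestling = if (!is.na(hatch)) c(hatch + 8L, hatch + 15L),
    fledging = if (!is.na(hatch)) c(hatch + 16L, hatch + 21L))
  structure(per, class = "reproductive_periods")
}

#' @export
print.reproductive_periods <- function(x, ...) {
  for (p in names(x)) {
    if (is.null(x[[p]])) cat(sprintf("  %-10s undefined\n", p))
    else cat(sprintf("  %-10s April-days %d..%d (%d d)\n", p,
                     x[[p]][1L], x[[p]][2L], diff(x[[p]]) + 1L))
  }
  invisible(x)
}

# Long table of period bounds for a whole attempts table (vectorized).
period_bounds_table <- function(attempts) {
  lay <- attempts$laying_april_day
  inc <- attempts$incubation_start_april_day
  inc <- ifelse(is.na(inc), lay + attempts$clutch_size, inc)
  hatch <- attempts$hatch_april_day
  n <- nrow(attempts)
  starts <- cbind(laying = lay, incubation = inc, hatching = hatch,
                  nestling = hatch + 8L, fledging = hatch + 16L)
  ends <- cbind(laying = inc - 1L, incubation = hatch - 1L,
                hatching = hatch + 7L, nestling = hatch + 15L,
                fledging = hatch + 21L)
  out <- data.frame(attempt_id = rep(attempts$attempt_id, times = 5L),
                    year = rep(attempts$year, times = 5L),
                    period = rep(.PERIODS, each = n),
                    start_april_day = as.integer(starts[seq_len(n * 5L)]),
                    end_april_day = as.integer(ends[seq_len(n * 5L)]))
  out[!is.na(out$start_april_day) & !is.na(out$end_april_day), ,
      drop = FALSE]
}

#' Per-attempt mean temperatures in the relative reproductive periods
#'
#' Matches the daily temperature series with each attempt's own
#' reproductive windows from [relative_period_bounds]. A window mean is
#' reported when at least `min_coverage` of its days are present (missing
#' count recorded); windows below that, or outside the series, are dropped
#' with a warning.
#'
#' @param attempts A `breeding_attempts` table.
#' @param series A [daily_temps] series.
#' @param min_coverage Minimum fraction of window days required (default
#'   0.5).
#' @return Data frame `attempt_id`, `year`, `period`, `start_april_day`,
#'   `end_april_day`, `mean_temp`, `n_days`, `n_missing`.
#' @export
relative_period_temperatures <- function(attempts, series,
                                         min_coverage = 0.5) {
  stopifnot(inherits(attempts, "breeding_attempts"),
            inherits(series, "daily_temps"))
  bounds <- period_bounds_table(attempts)
  m <- temp_matrix(series)
  # cumulative sums with NA as 0, plus a presence counter, per year row
  vals <- ifelse(is.na(m), 0, m)
  cs <- cbind(0, t(apply(vals, 1L, cumsum)))
  cn <- cbind(0L, t(apply(!is.na(m), 1L, cumsum)))
  row <- match(bounds$year, as.integer(rownames(m)))
  s <- april_day_to_doy(bounds$start_april_day)
  e <- april_day_to_doy(bounds$end_april_day)
  if (any(is.na(row)) || any(s < 1L) || any(e > 365L))
    stop("period windows fall outside the temperature series coverage")
  tot <- cs[cbind(row, e + 1L)] - cs[cbind(row, s)]
  npres <- cn[cbind(row, e + 1L)] - cn[cbind(row, s)]
  width <- e - s + 1L
  bounds$mean_temp <- ifelse(npres > 0L, tot / npres, NA_real_)
  bounds$n_days <- as.integer(npres)
  bounds$n_missing <- as.integer(width - npres)
  ok <- npres >= pmax(1L, ceiling(min_coverage * width))
  if (any(!ok))
    warning(sum(!ok), " period window(s) dropped for insufficient ",
            "temperature coverage")
  out <- bounds[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate calendar windows of consecutive days
#'
#' All contiguous closed windows of each length between `min_len` and
#' `max_len` (inclusive bounds) lying fully inside `[start, end]`, start
#' stepping by one day; ordered by length then start. With the default
#' breeding-season span of 111 days and lengths 8 to 15 this yields the
#' 804 windows of the window-slope distribution.
#'
#' @param start,end Month-day anchors `"MM-DD"`.
#' @param min_len,max_len Window lengths in days (inclusive).
#' @return Data frame `start_doy`, `end_doy`, `length`, `start_md`,
#'   `end_md`.
#' @export
enumerate_calendar_windows <- function(start = "02-15", end = "06-05",
                                       min_len = 8L, max_len = 15L) {
  s0 <- md_to_doy(start); e0 <- md_to_doy(end)
  span <- e0 - s0 + 1L
  if (min_len > max_len) stop("min_len exceeds max_len")
  if (max_len > span)
    stop("max_len (", max_len, ") exceeds the span (", span, " days)")
  out <- do.call(rbind, lapply(seq.int(min_len, max_len), function(L) {
    st <- seq.int(s0, e0 - L + 1L)
    data.frame(start_doy = st, end_doy = st + L - 1L, length = L)
  }))
  out$start_md <- vapply(out$start_doy, doy_to_md, character(1))
  out$end_md <- vapply(out$end_doy, doy_to_md, character(1))
  out
}
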