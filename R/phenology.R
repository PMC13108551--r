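#' Half-fall date of a yearly caterpillar series
#'
#' The earliest date by which the cumulative trap count reaches 50% of the
#' seasonal total (a threshold on counts, not days) - the standard index of
#' peak caterpillar availability. Integer dates; ties resolve to the
#' earliest qualifying date by construction.
#'
#' @param falls A `caterpillar_falls` table.
#' @param year Which year to use; may be omitted when the table holds one.
#' @return A `half_fall` list: `year`, `date`, `april_day`, `total_count`.
#' @export
half_fall_date <- function(falls, year = NULL) {
  stopifnot(inherits(falls, "caterpillar_falls"))
  if (is.null(year)) {
    yrs <- unique(falls$year)
    if (length(yrs) != 1L)
      stop("table holds ", length(yrs), " years; say which")
    year <- yrs
  }
  sub <- falls[falls$year == year, , drop = FALSE]
  if (!nrow(sub)) stop("no counts for year ", year)
  total <- sum(sub$count)
  if (total == 0L) stop("zero seasonal total in ", year,
                        "; half-fall undefined (unusable year)")
  sub <- sub[order(sub$doy), , drop = FALSE]
  i <- which(cumsum(sub$count) >= total / 2)[1L]
  structure(list(year = as.integer(year), date = sub$date[i],
                 april_day = sub$april_day[i], total_count = total),
            class = "half_fall")
}

#' @export
print.half_fall <- function(x, ...) {
  cat(sprintf("<half_fall> %d: %s (April-day %d), seasonal total %d\n",
              x$year, format(x$date), x$april_day, x$total_count))
  invisible(x)
}

#' Half-fall dates for every usable year of a caterpillar table
#'
#' @param falls A `caterpillar_falls` table.
#' @return Data frame `year`, `date`, `april_day`, `total_count`, one row
#'   per usable (positive-total) year; unusable years are skipped with a
#'   warning.
#' @export
half_fall_table <- function(falls) {
  stopifnot(inherits(falls, "caterpillar_falls"))
  ok <- usable_years(falls)
  skipped <- setdiff(unique(falls$year), ok)
  if (length(skipped))
    warning("year(s) with zero seasonal total skipped: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(ok, function(y) {
    hf <- half_fall_date(falls, y)
    data.frame(year = hf$year, date = hf$date, april_day = hf$april_day,
               total_count = hf$total_count)
  })
  do.call(rbind, rows)
}

#' Linear trend in half-fall date across years
#'
#' OLS of the April-day half-fall date on year, the caterpillar analogue of
#' the laying-date trend.
#'
#' @param half_falls Data frame from [half_fall_table].
#' @return A `trend_fit`.
#' @export
half_fall_trend <- function(half_falls) {
  fit_annual_trend(data.frame(year = half_falls$year,
                              value = half_falls$april_day))
}

#' Mean temperature in a window centered on each year's half-fall date
#'
#' Averages daily temperature over `[HF - halfwidth, HF + halfwidth]`
#' (15 days at the default +/- 7; +/- 15 and +/- 20 supported for
#' sensitivity checks). Same missing-day policy as the relative intervals:
#' reported when at least half the days are present.
#'
#' @param series A [daily_temps] series.
#' @param half_falls Data frame from [half_fall_table].
#' @param halfwidth Days either side of the half-fall date (default 7).
#' @return An `annual_series` (`year`, `value`, `n_days`, `n_missing`,
#'   `flagged`).
#' @export
temperature_at_half_fall <- function(series, half_falls, halfwidth = 7L) {
  m <- temp_matrix(series)
  row <- match(half_falls$year, as.integer(rownames(m)))
  if (anyNA(row)) stop("temperature series misses half-fall year(s)")
  doy <- april_day_to_doy(half_falls$april_day)
  s <- doy - halfwidth; e <- doy + halfwidth
  if (any(s < 1L) || any(e > 365L))
    stop("half-fall window leaves the 365-day grid")
  width <- 2L * halfwidth + 1L
  vals <- t(vapply(seq_along(row), function(i) {
    v <- m[row[i], s[i]:e[i]]
    c(mean(v, na.rm = TRUE), sum(!is.na(v)))
  }, numeric(2)))
  out <- data.frame(year = half_falls$year, value = vals[, 1L],
                    n_days = as.integer(vals[, 2L]),
                    n_missing = width - as.integer(vals[, 2L]))
  out$flagged <- out$n_days < ceiling(width / 2)
  out$value[out$n_days == 0L] <- NA_real_
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Trophic match between nestling demand and caterpillar availability
#'
#' `match = (hatch date + 10) - half-fall date` on the April-day scale:
#' nestling energetic demand peaks around day 10, so a zero match means the
#' brood's hungriest days coincide with peak food. `abs_mismatch` is its
#' absolute value. Attempts without a hatch date or without a half-fall
#' record for their year are absent from the result (count attached as
#' attribute `"n_dropped"`).
#'
#' @param attempts A `breeding_attempts` table.
#' @param half_falls Data frame from [half_fall_table].
#' @return Data frame `attempt_id`, `year`, `match_days`, `abs_mismatch`.
#' @export
compute_match <- function(attempts, half_falls) {
  hf <- half_falls$april_day[match(attempts$year, half_falls$year)]
  match_days <- attempts$hatch_april_day + 10L - hf
  ok <- !is.na(match_days)
  out <- data.frame(attempt_id = attempts$attempt_id[ok],
                    year = attempts$year[ok],
                    match_days = as.integer(match_days[ok]),
                    abs_mismatch = abs(as.integer(match_days[ok])))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Spline curve of absolute mismatch against period temperature
#'
#' Gaussian-response analogue of [fit_fitness_response]: absolute mismatch
#' on a natural cubic spline (default 7 df) of the period's temperature
#' with year and female random intercepts, for the laying, incubation,
#' hatching and nestling periods (the fledging period falls mostly after
#' the food peak and is excluded). The temperature minimizing predicted
#' mismatch is located with the same year-cluster bootstrap as the fitness
#' peaks; a flat curve is reported non-identifiable.
#'
#' @inheritParams fit_fitness_response
#' @param mismatch Mismatch table from [compute_match].
#' @param n_boot,seed Bootstrap resamples and seed for the minimizer
#'   interval.
#' @return List of class `mismatch_curve`: the `fitness_fit`-style model
#'   object (`fit`) and the `minimum` (`peak_estimate`, direction "min").
#' @export
mismatch_temperature_curve <- function(attempts, interval_temps, mismatch,
                                       period = c("laying", "incubation",
                                                  "hatching", "nestling"),
                                       spec = spline_spec(),
                                       n_boot = 500L, seed = 1L) {
  period <- match.arg(period)
  df <- .assemble_model_data(attempts, interval_temps, period, mismatch)
  fit <- .fit_spline_glmm(df, "abs_mismatch", "gaussian", spec, period,
                          grid_step = 0.1)
  minimum <- locate_peak_with_interval(fit, n_boot = n_boot, seed = seed,
                                       direction = "min")
  structure(list(fit = fit, minimum = minimum, period = period),
            class = "mismatch_curve")
}

#' @export
print.mismatch_curve <- function(x, ...) {
  cat(sprintf("<mismatch_curve> abs mismatch vs %s-period temperature, n = %d\n",
              x$period, x$fit$n_obs))
  print(x$minimum)
  invisible(x)
}

#' Annual mean laying dates of a breeding table
#'
#' @param attempts A `breeding_attempts` table.
#' @return An `annual_series` (`year`, `value` = mean April-day, `se`,
#'   `n`).
#' @export
annual_laying_means <- function(attempts) {
  sp <- split(attempts$laying_april_day, attempts$year)
  out <- data.frame(year = as.integer(names(sp)),
                    value = vapply(sp, mean, numeric(1)),
                    se = vapply(sp, function(v)
                      stats::sd(v) / sqrt(length(v)), numeric(1)),
                    n = lengths(sp))
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Sliding-window search for the laying cue window
#'
#' For every candidate calendar window, regresses the annual mean laying
#' date on the window's annual mean temperature and ranks the candidates
#' by small-sample-corrected AIC (equivalent to R^2 ranking for a fixed
#' year count and a single predictor). Years missing any day inside a
#' candidate window are dropped for that candidate.
#'
#' @param annual_laying An `annual_series` of mean laying dates (from
#'   [annual_laying_means]).
#' @param series A [daily_temps] series.
#' @param candidates Data frame from [enumerate_calendar_windows].
#' @return A `cue_window_search` list: `best` (one-row data frame) and
#'   `support` (all candidates with slope, R^2, AICc and delta-AICc,
#'   ranked).
#' @export
cue_window_search <- function(annual_laying, series, candidates) {
  if (!nrow(candidates)) stop("no candidate windows")
  if (nrow(annual_laying) < 10L)
    stop("need at least 10 years of laying data")
  m <- temp_matrix(series)
  years <- as.integer(rownames(m))
  lay <- annual_laying$value[match(years, annual_laying$year)]
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    doys <- candidates$start_doy[i]:candidates$end_doy[i]
    x <- rowMeans(m[, doys, drop = FALSE])      # NA if any day missing
    ok <- is.finite(x) & is.finite(lay)
    if (sum(ok) < 10L) return(NULL)
    fit <- stats::lm(lay[ok] ~ x[ok])
    data.frame(candidates[i, c("start_doy", "end_doy", "length",
                               "start_md", "end_md")],
               slope = stats::coef(fit)[[2L]],
               r_squared = summary(fit)$r.squared,
               aicc = aicc(fit), n_years = sum(ok))
  })
  support <- do.call(rbind, rows)
  if (is.null(support) || !nrow(support))
    stop("no candidate window had enough complete years")
  support <- support[order(support$aicc), , drop = FALSE]
  support$delta_aicc <- support$aicc - support$aicc[1L]
  rownames(support) <- NULL
  structure(list(best = support[1L, , drop = FALSE], support = support),
            class = "cue_window_search")
}

#' @export
print.cue_window_search <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<cue_window_search> best window %s..%s (%d d): slope %.2f d/degC, R2 %.3f, %d candidates\n",
    b$start_md, b$end_md, b$length, b$slope, b$r_squared,
    nrow(x$support)))
  invisible(x)
}
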