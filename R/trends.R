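#' Annual linear trend by ordinary least squares
#'
#' Fits `value ~ year` on one observation per year and reports the slope
#' (units per year) with its SE, the slope F statistic (`t^2` on 1 and
#' `n - 2` df), p value and a 95% Wald interval.
#'
#' @param annual An `annual_series` data frame (columns `year`, `value`),
#'   or any data frame with those columns.
#' @param use_flagged Include years flagged for missing coverage (default
#'   `TRUE`).
#' @return A `trend_fit` list.
#' @export
fit_annual_trend <- function(annual, use_flagged = TRUE) {
  df <- as.data.frame(annual)
  if (!all(c("year", "value") %in% names(df)))
    stop("need columns `year` and `value`")
  if (!use_flagged && "flagged" %in% names(df))
    df <- df[!df$flagged, , drop = FALSE]
  df <- df[is.finite(df$value), , drop = FALSE]
  n <- nrow(df)
  if (n < 3L) stop("need at least 3 years, got ", n)
  if (length(unique(df$year)) < 2L) stop("year is constant; rank-deficient")
  fit <- stats::lm(value ~ year, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(slope = co["year", "Estimate"],
                 slope_se = co["year", "Std. Error"],
                 intercept = co["(Intercept)", "Estimate"],
                 F_stat = co["year", "t value"]^2,
                 df = c(1L, n - 2L),
                 p_value = co["year", "Pr(>|t|)"],
                 ci = co["year", "Estimate"] +
                   c(-1, 1) * 1.96 * co["year", "Std. Error"],
                 r_squared = sm$r.squared,
                 n = n,
                 model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<trend_fit> slope %.*f +/- %.*f per yr, F(%d,%d) = %.2f, p = %.3g, n = %d\n",
    digits, x$slope, digits, x$slope_se, x$df[1L], x$df[2L], x$F_stat,
    x$p_value, x$n))
  invisible(x)
}

#' Attempt-level trend with year and female random intercepts
#'
#' Linear mixed model `response ~ year + (1 | year) + (1 | female)` fitted
#' by REML, controlling for the non-independence of attempts within years
#' and within females while estimating the fixed continuous-year slope.
#' The denominator df of the slope test uses the Satterthwaite
#' approximation; the 95% interval is Wald. Singular fits (a variance
#' component at zero) are reported with a flag, not an error.
#'
#' @param data Data frame of attempt-level observations.
#' @param value_col Name of the response column.
#' @param year_col,female_col Grouping columns (year doubles as the
#'   continuous fixed covariate, centered internally).
#' @param ddf Denominator-df method for the slope test:
#'   `"satterthwaite"` (default; fractional df and a t-based p value) or
#'   `"wald"` (normal approximation, `satterthwaite_df = NA`; noticeably
#'   faster, used by the large replicate batteries where only the Wald
#'   interval matters).
#' @return A `mixed_trend_fit` list: `fixed_slope`, `fixed_slope_se`,
#'   `satterthwaite_df`, `p_value`, `ci`, `variance_components`, `n_obs`,
#'   `n_groups`, `singular`.
#' @export
fit_attempt_level_trend <- function(data, value_col = "value",
                                    year_col = "year",
                                    female_col = "female_id",
                                    ddf = c("satterthwaite", "wald")) {
  ddf <- match.arg(ddf)
  df <- data.frame(value = as.numeric(data[[value_col]]),
                   year_c = as.numeric(data[[year_col]]) -
                     mean(as.numeric(data[[year_col]])),
                   year_f = factor(data[[year_col]]),
                   female = factor(data[[female_col]]))
  df <- df[is.finite(df$value), , drop = FALSE]
  if (nlevels(droplevels(df$year_f)) < 2L ||
      nlevels(droplevels(df$female)) < 2L)
    stop("need at least 2 levels of year and of female")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  if (ddf == "satterthwaite") {
    fit <- suppressMessages(lmerTest::lmer(
      value ~ year_c + (1 | year_f) + (1 | female), data = df, REML = TRUE,
      control = ctrl))
    co <- stats::coef(summary(fit))
  } else {
    fit <- suppressMessages(lme4::lmer(
      value ~ year_c + (1 | year_f) + (1 | female), data = df, REML = TRUE,
      control = ctrl))
    co0 <- stats::coef(summary(fit))
    co <- cbind(co0, df = NA_real_,
                `Pr(>|t|)` = 2 * stats::pnorm(-abs(co0[, "t value"])))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  comps <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                           ifelse(vc$grp == "year_f", "year",
                                                  "female")))
  structure(list(fixed_slope = co["year_c", "Estimate"],
                 fixed_slope_se = co["year_c", "Std. Error"],
                 satterthwaite_df = co["year_c", "df"],
                 p_value = co["year_c", "Pr(>|t|)"],
                 ci = co["year_c", "Estimate"] +
                   c(-1, 1) * 1.96 * co["year_c", "Std. Error"],
                 variance_components = comps,
                 n_obs = nrow(df),
                 n_groups = c(year = nlevels(droplevels(df$year_f)),
                              female = nlevels(droplevels(df$female))),
                 singular = lme4::isSingular(fit),
                 model = fit),
            class = "mixed_trend_fit")
}

#' @export
print.mixed_trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<mixed_trend_fit> slope %.*f +/- %.*f per yr, t df (Satterthwaite) %.1f, p = %.3g\n",
    digits, x$fixed_slope, digits, x$fixed_slope_se, x$satterthwaite_df,
    x$p_value))
  cat(sprintf("  n = %d obs, %d years, %d females%s\n", x$n_obs,
              x$n_groups[["year"]], x$n_groups[["female"]],
              if (x$singular) " [singular fit: a variance component is 0]"
              else ""))
  cat("  variance components:",
      paste(sprintf("%s %.3g", names(x$variance_components),
                    x$variance_components), collapse = ", "), "\n")
  invisible(x)
}

#' Trend slopes for every candidate calendar window
#'
#' For each enumerated window, computes the yearly mean temperature inside
#' it and fits the same annual OLS trend as the fixed interval; returns all
#' per-window slopes with their mean and SD, i.e. the window-slope
#' distribution that checks whether fixed-versus-relative differences are
#' an artefact of interval length. Years with any missing day inside a
#' window are dropped for that window.
#'
#' @param series A [daily_temps] series.
#' @param windows Data frame from [enumerate_calendar_windows].
#' @return A `window_slopes` list: `slopes` (per-window data frame),
#'   `mean_slope`, `sd_slope`, `n_windows`.
#' @export
sliding_window_slope_distribution <- function(series, windows) {
  if (!nrow(windows)) stop("no candidate windows")
  m <- temp_matrix(series)
  years <- as.integer(rownames(m))
  vals <- ifelse(is.na(m), 0, m)
  cs <- cbind(0, t(apply(vals, 1L, cumsum)))
  cn <- cbind(0L, t(apply(!is.na(m), 1L, cumsum)))
  res <- vapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start_doy[i]; e <- windows$end_doy[i]
    npres <- cn[, e + 1L] - cn[, s]
    y <- (cs[, e + 1L] - cs[, s]) / npres
    ok <- npres == (e - s + 1L)
    x <- years[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) return(c(NA_real_, NA_real_, n))
    xc <- x - mean(x)
    slope <- sum(xc * y) / sum(xc^2)
    resid <- y - mean(y) - slope * xc
    se <- sqrt(sum(resid^2) / (n - 2L) / sum(xc^2))
    c(slope, se, n)
  }, numeric(3))
  slopes <- cbind(windows[, c("start_doy", "end_doy", "length", "start_md",
                              "end_md")],
                  slope = res[1L, ], se = res[2L, ], n_years = res[3L, ])
  structure(list(slopes = slopes,
                 mean_slope = mean(res[1L, ], na.rm = TRUE),
                 sd_slope = stats::sd(res[1L, ], na.rm = TRUE),
                 n_windows = nrow(windows)),
            class = "window_slopes")
}

#' @export
print.window_slopes <- function(x, ...) {
  cat(sprintf(
    "<window_slopes> %d windows: mean slope %.4f +/- %.4f (SD) per yr\n",
    x$n_windows, x$mean_slope, x$sd_slope))
  invisible(x)
}

#' @export
plot.window_slopes <- function(x, fixed_slope = NULL, ...) {
  d <- stats::density(x$slopes$slope[is.finite(x$slopes$slope)])
  graphics::plot(d, main = "Calendar-window trend slopes",
                 xlab = "slope (per yr)", ...)
  if (!is.null(fixed_slope)) graphics::abline(v = fixed_slope, lty = 2)
  invisible(x)
}
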